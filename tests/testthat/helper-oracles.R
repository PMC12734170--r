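# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately avoid the package's
# computational paths: windows are materialised explicitly from a padded
# copy, distances come from double loops over pixel pairs, and confusion
# counts from per-pixel loops.

# symmetric reflective padding by explicit index vectors
oraclePad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(p:1, 1:nr, nr:(nr - p + 1)), c(p:1, 1:nc, nc:(nc - p + 1))]
}

# windowed population variance by direct window extraction
oracleContrast <- function(frame, w) {
  p <- (w - 1) / 2
  pad <- oraclePad(frame, p)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- pad[r:(r + w - 1), c:(c + w - 1)]
    out[r, c] <- mean((win - mean(win))^2)
  }
  out
}

# windowed Shannon entropy by direct histogramming of quantised levels
oracleEntropy <- function(frame, w, L, eps = 2^-52) {
  q <- pmin(floor(frame * L), L - 1)
  p <- (w - 1) / 2
  pad <- oraclePad(q, p)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- pad[r:(r + w - 1), c:(c + w - 1)]
    pk <- tabulate(win + 1L, nbins = L) / (w * w)
    out[r, c] <- -sum(pk * log2(pk + eps))
  }
  out
}

# confusion counts by a per-pixel loop
oracleConfusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1L) {
      if (gt[i] == 1L) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (gt[i] == 1L) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# per-point distance to the nearest skeleton pixel by a double loop
oracleNearest <- function(path, skelPix) {
  if (nrow(skelPix) == 0L) return(rep(Inf, nrow(path)))
  vapply(seq_len(nrow(path)), function(i) {
    min(sqrt((skelPix[, 1] - path[i, 1])^2 +
             (skelPix[, 2] - path[i, 2])^2))
  }, numeric(1))
}

# arc length of a run of consecutive path indices; single point counts 1
oracleRunLength <- function(path, idx) {
  if (length(idx) == 1L) return(1)
  steps <- sqrt(rowSums((path[idx[-1L], , drop = FALSE] -
                         path[idx[-length(idx)], , drop = FALSE])^2))
  sum(steps)
}

# Vessel Connectivity recomputed from the segment decomposition with
# brute-force nearest distances and explicit unmatched-run bookkeeping
oracleVC <- function(gt, pred, rMatch = 2) {
  skelG <- skeletonizeMask(gt)
  skelP <- skeletonizeMask(pred)
  segs <- decomposeSegments(skelG)
  pix <- skeletonPixels(skelP)
  ce <- vapply(segs@paths, function(path) {
    d <- oracleNearest(path, pix)
    matched <- d <= rMatch
    m <- if (any(matched)) mean(d[matched]) else 0
    pen <- 0
    i <- 1L
    while (i <= length(d)) {
      if (!matched[i]) {
        j <- i
        while (j < length(d) && !matched[j + 1L]) j <- j + 1L
        pen <- pen + oracleRunLength(path, i:j)
        i <- j + 1L
      } else i <- i + 1L
    }
    m + pen
  }, numeric(1))
  if (length(ce)) mean(ce) else 0
}

# 8-connected component count by BFS flood fill
componentCount8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  idx <- which(mask == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1]; c0 <- idx[k, 2]
    if (lab[r0, c0] != 0L) next
    comp <- comp + 1L
    queue <- matrix(c(r0, c0), 1L, 2L)
    lab[r0, c0] <- comp
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] == 1L && lab[rr, cc] == 0L) {
          lab[rr, cc] <- comp
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  comp
}

# straight single-trunk tree fixture
trunkTree <- function(size = 64, radius = 2, row = NULL, flowSpeed = 300) {
  if (is.null(row)) row <- size / 2
  nodes <- rbind(c(row, 6), c(row, size - 6))
  len <- sqrt(sum((nodes[2, ] - nodes[1, ])^2))
  new("VesselTree", nodes = nodes,
      edges = data.frame(from = 1L, to = 2L, radius = radius, depth = 0L),
      arrival = c(0, len / flowSpeed), root = 1, size = c(size, size))
}

# small seeded phantom bundle used by several tests
makePhantom <- function(seed, size = 256, noiseSd = 10 / 255, ...) {
  cfg <- phantomConfig(size = size, noiseSd = noiseSd, ...)
  tree <- generateTree(cfg, seed)
  sim <- simulateSequence(tree, cfg, seed)
  c(sim, list(cfg = cfg, tree = tree))
}

# cut disks of the local vessel half-width along given skeleton-path
# pixels (deterministic gap cutter for nested-degradation tests)
cutAlongPath <- function(mask, path, idx) {
  radius <- matrix(as.numeric(EBImage::distmap(mask)), nrow(mask), ncol(mask))
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (k in idx) {
    p <- path[k, ]; r <- radius[p[1], p[2]] + 1
    rr <- max(1, floor(p[1] - r)):min(h, ceiling(p[1] + r))
    cc <- max(1, floor(p[2] - r)):min(w, ceiling(p[2] + r))
    d2 <- outer((rr - p[1])^2, (cc - p[2])^2, `+`)
    block <- out[rr, cc, drop = FALSE]
    block[d2 <= r^2] <- 0L
    out[rr, cc] <- block
  }
  out
}
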