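# Synthetic angiography phantoms with exact ground truth: a bifurcating
# vessel tree entering from the image border, rasterized as disks swept
# along its centerline polylines, filled over time by a contrast bolus
# travelling at fixed speed, on a smooth background with bone-like dark
# band artifacts and additive Gaussian noise. Everything is a
# deterministic function of (config, seed).

#' Generate a random bifurcating vessel tree
#'
#' A trunk grows inward from a border root and bifurcates recursively up
#' to \code{depth} levels; segment lengths and radii decay geometrically
#' with depth, branch angles are drawn from the configured range, and
#' branches that would leave the image are steered inward (and dropped if
#' that fails). Per-node bolus arrival times are centerline path length
#' from the root divided by the flow speed.
#'
#' @param cfg a \code{\link{PhantomConfig}}
#' @param seed integer seed; the same seed reproduces the tree exactly
#' @return a \code{\link{VesselTree}}
#' @export
generateTree <- function(cfg, seed) {
  .withSeed(seed, {
    h <- cfg@size[1]; w <- cfg@size[2]
    margin <- max(4, cfg@rootRadius + 2)
    nodes <- matrix(c(h / 2 * runif(1, 0.7, 1.3), 1), 1L, 2L)
    edges <- data.frame(from = integer(), to = integer(),
                        radius = numeric(), depth = integer())
    arrival <- 0

    inBounds <- function(p)
      p[1] >= margin && p[1] <= h - margin &&
      p[2] >= margin && p[2] <= w - margin

    grow <- function(parent, angle, depth) {
      len <- cfg@branchLength * cfg@lengthDecay^depth * runif(1, 0.85, 1.15)
      radius <- max(1, cfg@rootRadius * cfg@radiusDecay^depth)
      from <- nodes[parent, ]
      end <- NULL
      for (steer in c(0, -20, 20, -40, 40, -60, 60)) {
        a <- (angle + steer) * pi / 180
        cand <- from + len * c(sin(a), cos(a))
        if (inBounds(cand)) { end <- cand; angle <- angle + steer; break }
      }
      if (is.null(end)) return(invisible(NULL))
      nodes <<- rbind(nodes, end)
      child <- nrow(nodes)
      edges[nrow(edges) + 1L, ] <<- list(parent, child, radius,
                                         as.integer(depth))
      arrival[child] <<- arrival[parent] + len / cfg@flowSpeed
      if (depth < cfg@depth) {
        half <- runif(2, cfg@angleRange[1], cfg@angleRange[2])
        grow(child, angle - half[1], depth + 1)
        grow(child, angle + half[2], depth + 1)
      }
      invisible(NULL)
    }

    grow(1L, runif(1, -15, 15), 0)
    dimnames(nodes) <- NULL
    new("VesselTree", nodes = nodes, edges = edges, arrival = arrival,
        root = 1, size = cfg@size)
  })
}

# per-pixel bolus arrival map (+Inf on background) and projection profile:
# the earliest arrival among all covering centerline disks, and the
# chord-length fraction of a projected cylinder (1 on the centerline,
# falling towards the lumen boundary), which gives wide vessels the
# interior intensity structure a real X-ray projection has
.rasterizeArrival <- function(tree, size) {
  if (length(size) == 1L) size <- c(size, size)
  h <- size[1]; w <- size[2]
  arr <- matrix(Inf, h, w)
  prof <- matrix(0, h, w)
  e <- tree@edges
  for (k in seq_len(nrow(e))) {
    a <- tree@nodes[e$from[k], ]; b <- tree@nodes[e$to[k], ]
    ta <- tree@arrival[e$from[k]]; tb <- tree@arrival[e$to[k]]
    r <- e$radius[k]
    len <- sqrt(sum((b - a)^2))
    nStep <- max(2L, ceiling(len / 0.7) + 1L)
    ts <- seq(0, 1, length.out = nStep)
    for (s in ts) {
      p <- a + s * (b - a)
      tArr <- ta + s * (tb - ta)
      r0 <- max(1L, floor(p[1] - r - 0.5)); r1 <- min(h, ceiling(p[1] + r + 0.5))
      c0 <- max(1L, floor(p[2] - r - 0.5)); c1 <- min(w, ceiling(p[2] + r + 0.5))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - p[1])^2, (cc - p[2])^2, `+`)
      hit <- d2 <= (r + 0.5)^2  # pixel-coverage radius
      aBlock <- arr[rr, cc, drop = FALSE]
      upd <- hit & tArr < aBlock
      aBlock[upd] <- tArr
      arr[rr, cc] <- aBlock
      chord <- sqrt(pmax(0, 1 - d2 / (r + 0.5)^2)) * hit
      pBlock <- prof[rr, cc, drop = FALSE]
      prof[rr, cc] <- pmax(pBlock, chord)
    }
  }
  list(arrival = arr, profile = prof)
}

#' Rasterize a vessel tree as a binary mask
#'
#' The union of disks of each edge's radius swept along its centerline;
#' the result is a single connected component whose skeleton approximates
#' the tree centerlines.
#'
#' @param tree a \code{\link{VesselTree}}
#' @param size image size (rows, cols); defaults to the tree's own
#' @return binary matrix
#' @export
rasterizeMask <- function(tree, size = tree@size) {
  .asMask((.rasterizeArrival(tree, size)$arrival < Inf) * 1L)
}

# smooth low-frequency field in [-1, 1]: a few random cosine gratings
.smoothField <- function(h, w, nWaves = 3L) {
  f <- matrix(0, h, w)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nWaves)) {
    th <- runif(1, 0, pi); freq <- runif(1, 0.5, 1.5); ph <- runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * freq * (rr * sin(th) + cc * cos(th)) /
                   max(h, w) + ph)
  }
  rng <- range(f)
  if (rng[2] - rng[1] <= 0) return(f * 0)
  2 * (f - rng[1]) / (rng[2] - rng[1]) - 1
}

# bone-like clutter: dark bands with sharp edges along random lines
.boneField <- function(h, w, count, depth) {
  f <- matrix(0, h, w)
  if (count < 1) return(f)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(count)) {
    th <- runif(1, 0, pi)
    nvec <- c(cos(th), -sin(th))
    offset <- runif(1, 0.25, 0.75) * (abs(nvec[1]) * h + abs(nvec[2]) * w)
    halfWidth <- runif(1, 2, 5)
    d <- abs(rr * nvec[1] + cc * nvec[2] - offset)
    f <- f - depth * runif(1, 0.8, 1.2) * (d <= halfWidth)
  }
  f
}

#' Simulate a time-sequential angiography phantom
#'
#' Frame i (time t = (i-1)/frameRate) darkens the vessel pixels whose
#' bolus arrival time is at most t, over a smooth bright background with
#' bone-like dark band artifacts; Gaussian noise is added per frame and
#' frames are quantised to 8-bit vessel-dark polarity. Per-frame ground
#' truth is the filled-so-far mask (nested over time) and the full mask
#' covers the whole tree. With zero noise, the minimum intensity
#' projection equals the final fully-filled vessel image wherever the
#' bolus has arrived by the last frame.
#'
#' @param tree a \code{\link{VesselTree}}
#' @param cfg a \code{\link{PhantomConfig}}
#' @param seed integer seed for frame count and noise
#' @return list with \code{sequence} (vessel-dark \code{DSASequence}),
#'   \code{frameMasks} (list of per-frame binary masks),
#'   \code{fullMask} (binary mask of the whole tree) and
#'   \code{arrival} (the per-pixel arrival map)
#' @export
simulateSequence <- function(tree, cfg, seed) {
  .withSeed(seed, {
    h <- cfg@size[1]; w <- cfg@size[2]
    ras <- .rasterizeArrival(tree, cfg@size)
    arr <- ras$arrival
    nF <- if (is.na(cfg@nFrames)) sample(4:14, 1L) else cfg@nFrames
    bg <- cfg@backgroundLevel +
      cfg@backgroundAmplitude * .smoothField(h, w) +
      .boneField(h, w, cfg@boneCount, cfg@boneDepth)
    frames <- vector("list", nF)
    masks <- vector("list", nF)
    for (i in seq_len(nF)) {
      t <- (i - 1) / cfg@frameRate
      filled <- arr <= t
      img <- bg - cfg@vesselDepth * ras$profile * filled
      if (cfg@noiseSd > 0) img <- img + rnorm(h * w, 0, cfg@noiseSd)
      frames[[i]] <- round(.clamp(img, 0, 1) * 255)
      masks[[i]] <- .asMask(filled * 1L)
    }
    list(sequence = DSASequence(frames, polarity = "vessel_dark",
                                frameRate = cfg@frameRate,
                                grayLevels = 256, mode = "integer"),
         frameMasks = masks,
         fullMask = .asMask((arr < Inf) * 1L),
         arrival = arr)
  })
}

#' Apply controlled degradations to a binary mask
#'
#' Supported operators, given as a list of lists with an \code{op} field:
#' \describe{
#'   \item{\code{gap(length)}}{removes the mask around a run of
#'     \code{length} skeleton pixels, fragmenting a vessel}
#'   \item{\code{delete_branch(id)}}{removes one tree edge and all of its
#'     descendants (requires \code{tree})}
#'   \item{\code{dilate(r)}}{morphological dilation with a disc of radius r}
#'   \item{\code{shift(dx, dy)}}{translates the mask by (rows, cols)}
#'   \item{\code{speckle(n)}}{adds n isolated false-positive pixels away
#'     from the mask}
#' }
#' Deterministic per seed; an empty op list returns the mask unchanged.
#'
#' @param mask binary matrix
#' @param ops list of degradation operators
#' @param seed integer seed
#' @param tree the generating \code{\link{VesselTree}}, required by
#'   \code{delete_branch}
#' @return a degraded binary mask
#' @export
degradeMask <- function(mask, ops = list(), seed = 1, tree = NULL) {
  mask <- .asMask(mask)
  if (length(ops) == 0L) return(mask)
  .withSeed(seed, {
    for (op in ops) {
      mask <- switch(op$op,
        gap = .opGap(mask, op$length),
        delete_branch = .opDeleteBranch(mask, op$id, tree),
        dilate = .opDilate(mask, op$r),
        shift = .opShift(mask, op$dx, op$dy),
        speckle = .opSpeckle(mask, op$n),
        stop(sprintf("unknown degradation op '%s'", op$op)))
    }
    mask
  })
}

.opGap <- function(mask, len) {
  segs <- decomposeSegments(skeletonizeMask(mask))
  if (nSegments(segs) == 0L) return(mask)
  sizes <- vapply(segs@paths, nrow, integer(1))
  eligible <- which(sizes >= 3L)
  if (length(eligible) == 0L) eligible <- seq_along(sizes)
  pick <- eligible[sample.int(length(eligible), 1L)]
  path <- segs@paths[[pick]]
  n <- nrow(path)
  runLen <- min(len, n)
  start <- sample.int(max(1L, n - runLen + 1L), 1L)
  run <- path[start:(start + runLen - 1L), , drop = FALSE]
  radius <- .distanceToSet(1L - mask)  # distance to background = local halfwidth
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (k in seq_len(nrow(run))) {
    p <- run[k, ]; r <- radius[p[1], p[2]] + 1
    r0 <- max(1L, floor(p[1] - r)); r1 <- min(h, ceiling(p[1] + r))
    c0 <- max(1L, floor(p[2] - r)); c1 <- min(w, ceiling(p[2] + r))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - p[1])^2, (cc - p[2])^2, `+`)
    block <- out[rr, cc, drop = FALSE]
    block[d2 <= r^2] <- 0L
    out[rr, cc] <- block
  }
  .asMask(out)
}

.opDeleteBranch <- function(mask, id, tree) {
  if (is.null(tree)) stop("delete_branch requires the generating tree")
  e <- tree@edges
  if (!id %in% seq_len(nrow(e))) stop(sprintf("branch id %s absent", id))
  drop <- id
  repeat {
    more <- which(e$from %in% e$to[drop] & !seq_len(nrow(e)) %in% drop)
    if (length(more) == 0L) break
    drop <- c(drop, more)
  }
  sub <- function(idx) {
    t2 <- new("VesselTree", nodes = tree@nodes,
              edges = e[idx, , drop = FALSE], arrival = tree@arrival,
              root = tree@root, size = tree@size)
    rasterizeMask(t2, dim(mask))
  }
  keepIdx <- setdiff(seq_len(nrow(e)), drop)
  removed <- sub(drop)
  kept <- if (length(keepIdx)) sub(keepIdx) else mask * 0L
  .asMask(((mask == 1L) & !(removed == 1L & kept == 0L)) * 1L)
}

.opDilate <- function(mask, r) {
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  out <- EBImage::dilate(mask, brush)
  .asMask((matrix(as.numeric(out), nrow(mask), ncol(mask)) > 0) * 1L)
}

.opShift <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  rs <- seq_len(h) - dx; cs <- seq_len(w) - dy
  okR <- rs >= 1L & rs <= h; okC <- cs >= 1L & cs <= w
  out[okR, okC] <- mask[rs[okR], cs[okC]]
  .asMask(out)
}

.opSpeckle <- function(mask, n) {
  far <- .distanceToSet(mask) > 3
  out <- mask
  for (k in seq_len(n)) {
    cand <- which(far & .distanceToSet(out - mask) > 2)
    if (length(cand) == 0L) break
    i <- cand[sample.int(length(cand), 1L)]
    out[i] <- 1L
  }
  .asMask(out)
}
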