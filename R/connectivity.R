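# Topology-aware evaluation: binary thinning to 1-pixel centerlines,
# decomposition into junction-to-terminal segments, and the Vessel
# Connectivity metric -- the mean per-segment connectivity error between
# ground-truth and predicted centerlines, with arc-length penalties for
# unmatched sub-segments. 8-connectivity is used throughout; diagonal
# steps cost sqrt(2) of arc length.

# one Zhang-Suen subiteration; returns the deletable-pixel mask
.zsDeletable <- function(map, firstPass) {
  p <- .padZero(map, 1L)
  nr <- nrow(map); nc <- ncol(map)
  rs <- 1L + seq_len(nr); cs <- 1L + seq_len(nc)
  p2 <- p[rs - 1L, cs];      p3 <- p[rs - 1L, cs + 1L]
  p4 <- p[rs, cs + 1L];      p5 <- p[rs + 1L, cs + 1L]
  p6 <- p[rs + 1L, cs];      p7 <- p[rs + 1L, cs - 1L]
  p8 <- p[rs, cs - 1L];      p9 <- p[rs - 1L, cs - 1L]
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
       (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (firstPass) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  map == 1 & B >= 2 & B <= 6 & A == 1 & cond
}

#' Skeletonize a binary mask to a 1-pixel-wide centerline
#'
#' Zhang-Suen thinning: pixels are peeled from alternating sides until no
#' deletable pixel remains, yielding an 8-connected, one-pixel-wide medial
#' curve that preserves the mask's connected components. The operation is
#' idempotent, and an empty mask gives an empty skeleton.
#'
#' @param mask binary matrix
#' @return a \code{\link{Skeleton}}
#' @export
skeletonizeMask <- function(mask) {
  map <- .asMask(mask) + 0
  repeat {
    d1 <- .zsDeletable(map, TRUE);  map[d1] <- 0
    d2 <- .zsDeletable(map, FALSE); map[d2] <- 0
    if (!any(d1) && !any(d2)) break
  }
  new("Skeleton", map = .asMask(map))
}

# 8-neighbours of pixel (r, c) present in `map`, in deterministic
# (row-major) order
.skelNeighbors <- function(map, r, c) {
  nr <- nrow(map); nc <- ncol(map)
  out <- matrix(0L, 0L, 2L)
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && map[rr, cc] == 1L)
      out <- rbind(out, c(rr, cc))
  }
  out
}

#' Decompose a skeleton into vessel segments
#'
#' Junctions are skeleton pixels with 8-neighbour degree >= 3 and
#' endpoints those with degree 1. Segments are the ordered maximal paths
#' of non-junction pixels running junction-to-junction,
#' junction-to-endpoint or endpoint-to-endpoint; every non-junction
#' skeleton pixel belongs to exactly one segment. Isolated cycles are cut
#' at their lexicographically smallest pixel for determinism.
#'
#' @param skel a \code{\link{Skeleton}}
#' @return a \code{\link{SegmentSet}}
#' @export
decomposeSegments <- function(skel) {
  map <- skel@map
  deg <- .neighborCount8(map) * map
  junction <- map == 1L & deg >= 3L
  endpoint <- map == 1L & deg == 1L
  chain <- map == 1L & !junction
  chainIdx <- which(chain)
  paths <- list()

  if (length(chainIdx) > 0L) {
    nr <- nrow(map)
    visited <- matrix(FALSE, nr, ncol(map))
    chainMap <- chain * 1L

    walk <- function(r0, c0) {
      path <- matrix(c(r0, c0), 1L, 2L)
      visited[r0, c0] <<- TRUE
      repeat {
        cur <- path[nrow(path), ]
        nb <- .skelNeighbors(chainMap, cur[1L], cur[2L])
        if (nrow(nb) == 0L) break
        nb <- nb[!visited[nb], , drop = FALSE]
        if (nrow(nb) == 0L) break
        # prefer orthogonal continuation, then lexicographic order
        d <- abs(nb[, 1L] - cur[1L]) + abs(nb[, 2L] - cur[2L])
        nb <- nb[order(d, nb[, 1L], nb[, 2L]), , drop = FALSE]
        nxt <- nb[1L, ]
        visited[nxt[1L], nxt[2L]] <<- TRUE
        path <- rbind(path, nxt)
      }
      path
    }

    # chain pixels adjacent to at most one chain pixel start open paths
    starts <- chainIdx[vapply(chainIdx, function(i) {
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      nrow(.skelNeighbors(chainMap, r, c)) <= 1L
    }, logical(1))]
    for (i in starts) {
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      if (!visited[r, c]) paths[[length(paths) + 1L]] <- walk(r, c)
    }
    # remaining pixels belong to cycles; cut each at its smallest pixel
    repeat {
      left <- chainIdx[!visited[chainIdx]]
      if (length(left) == 0L) break
      pos <- cbind((left - 1L) %% nr + 1L, (left - 1L) %/% nr + 1L)
      o <- order(pos[, 1L], pos[, 2L])[1L]
      paths[[length(paths) + 1L]] <- walk(pos[o, 1L], pos[o, 2L])
    }
  }

  dimnamesless <- function(m) { dimnames(m) <- NULL; m }
  new("SegmentSet", paths = lapply(paths, dimnamesless),
      junctions = dimnamesless(which(junction, arr.ind = TRUE)),
      endpoints = dimnamesless(which(endpoint, arr.ind = TRUE)),
      lengths = vapply(paths, .arcLength, numeric(1)))
}

#' Connectivity error of one ground-truth segment
#'
#' Each centerline point is assigned the Euclidean distance to the nearest
#' predicted-skeleton pixel (via an exact distance transform); points with
#' distance at most \code{rMatch} are matched. The error is the mean
#' matched distance plus the summed arc lengths of all maximal runs of
#' consecutive unmatched points (a single isolated unmatched point
#' contributes 1). A fully unmatched segment scores its full arc length,
#' as does any segment against an empty prediction.
#'
#' @param path ordered n x 2 (row, col) pixel path of the segment
#' @param predSkeleton a \code{\link{Skeleton}} of the prediction
#' @param rMatch matching radius in pixels (default 2)
#' @param distMap optional precomputed distance-to-prediction matrix
#' @return non-negative connectivity error in pixels
#' @export
segmentCE <- function(path, predSkeleton, rMatch = 2, distMap = NULL) {
  if (nrow(path) == 0L) stop("segment path must be non-empty")
  if (is.null(distMap)) distMap <- .distanceToSet(predSkeleton@map)
  d <- distMap[path]
  matched <- d <= rMatch
  meanTerm <- if (any(matched)) mean(d[matched]) else 0
  penalty <- 0
  runs <- rle(!matched)
  stop_ <- cumsum(runs$lengths)
  start_ <- stop_ - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    penalty <- penalty +
      .arcLength(path[start_[k]:stop_[k], , drop = FALSE])
  }
  meanTerm + penalty
}

#' Vessel Connectivity between a ground-truth and a predicted mask
#'
#' Both masks are skeletonized; the ground-truth skeleton is decomposed
#' into S segments, and VC is the mean of the per-segment connectivity
#' errors against the predicted skeleton treated as a point set
#' (\code{\link{segmentCE}}). VC is 0 exactly when every ground-truth
#' centerline pixel lies on the predicted skeleton; lower is better.
#'
#' @param gt non-empty binary ground-truth mask
#' @param pred binary predicted mask
#' @param rMatch matching radius in pixels (default 2)
#' @return a \code{\link{VCResult}}
#' @export
vesselConnectivity <- function(gt, pred, rMatch = 2) {
  gt <- .asMask(gt, "gt"); pred <- .asMask(pred, "pred")
  if (!identical(dim(gt), dim(pred)))
    stop("shape mismatch between gt and pred")
  if (sum(gt) == 0L) stop("undefined metric: ground truth has no vessel pixels")
  skelG <- skeletonizeMask(gt)
  skelP <- skeletonizeMask(pred)
  segs <- decomposeSegments(skelG)
  distMap <- .distanceToSet(skelP@map)
  ce <- vapply(segs@paths, segmentCE, numeric(1),
               predSkeleton = skelP, rMatch = rMatch, distMap = distMap)
  nPts <- sum(vapply(segs@paths, nrow, integer(1)))
  nMatched <- sum(vapply(segs@paths,
                         function(p) sum(distMap[p] <= rMatch), numeric(1)))
  new("VCResult", vc = if (length(ce)) mean(ce) else 0,
      perSegmentCE = ce,
      matchedFraction = if (nPts) nMatched / nPts else 1,
      rMatch = rMatch)
}
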