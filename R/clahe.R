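# Contrast-limited adaptive histogram equalization, the comparison
# baseline. The frame is partitioned into tiles (the last row/column of
# tiles may be smaller); each tile's histogram is clipped, the excess is
# redistributed uniformly over all bins, and the clipped CDF defines the
# tile mapping (cdf - cdf_min) / (n_tile - cdf_min) * (G - 1). Per-pixel
# output interpolates the four surrounding tile mappings bilinearly, the
# standard way of avoiding tile-boundary seams.

# per-tile intensity mapping (vector over levels 0..G-1)
.claheTileMap <- function(v, G, clipCount) {
  n <- length(v)
  if (min(v) == max(v)) return(seq_len(G) - 1)  # constant tile: identity
  h <- tabulate(v + 1L, nbins = G)
  if (is.finite(clipCount)) {
    excess <- sum(pmax(h - clipCount, 0))
    h <- pmin(h, clipCount) + excess / G
  }
  cdf <- cumsum(h)
  cdfMin <- min(cdf[cdf > 0])
  denom <- n - cdfMin
  if (denom <= 0) return(seq_len(G) - 1)  # constant tile: identity
  .clamp((cdf - cdfMin) / denom * (G - 1), 0, G - 1)
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param frame integer-mode matrix with values in 0..grayLevels-1
#' @param grayLevels total number of gray levels G
#' @param tileSize tile size in pixels, (rows, cols) or a scalar; tiles
#'   partition the frame and the last tiles may be smaller
#' @param clipLimit histogram clip limit as a multiple of the mean bin
#'   height (counts above it are redistributed uniformly); \code{Inf}
#'   disables clipping
#' @return integer-mode matrix in 0..grayLevels-1
#' @export
claheEqualize <- function(frame, grayLevels = 256, tileSize = c(64, 64),
                          clipLimit = 4) {
  if (length(tileSize) == 1L) tileSize <- c(tileSize, tileSize)
  if (any(tileSize < 2)) stop("tile size must be >= 2 pixels")
  if (any(tileSize > dim(frame))) stop("tile larger than frame")
  if (clipLimit < 1) stop("clipLimit must be >= 1")
  G <- as.integer(grayLevels)
  if (min(frame) < 0 || max(frame) > G - 1)
    stop("frame values must lie in 0..G-1")
  v <- matrix(as.integer(round(frame)), nrow(frame), ncol(frame))
  nr <- nrow(v); nc <- ncol(v)
  rStarts <- seq(1L, nr, by = tileSize[1])
  cStarts <- seq(1L, nc, by = tileSize[2])
  rEnds <- c(rStarts[-1L] - 1L, nr)
  cEnds <- c(cStarts[-1L] - 1L, nc)
  nTr <- length(rStarts); nTc <- length(cStarts)
  rCenters <- (rStarts + rEnds) / 2
  cCenters <- (cStarts + cEnds) / 2

  maps <- array(0, dim = c(G, nTr, nTc))
  for (ti in seq_len(nTr)) for (tj in seq_len(nTc)) {
    tile <- v[rStarts[ti]:rEnds[ti], cStarts[tj]:cEnds[tj]]
    clipCount <- if (is.finite(clipLimit)) clipLimit * length(tile) / G else Inf
    maps[, ti, tj] <- .claheTileMap(as.vector(tile), G, clipCount)
  }

  # bilinear weights between neighbouring tile centers, clamped at borders
  tileCoord <- function(pos, centers) {
    k <- length(centers)
    lo <- .clamp(findInterval(pos, centers), 1L, max(k - 1L, 1L))
    hi <- pmin(lo + 1L, k)
    w <- ifelse(hi == lo, 0, (pos - centers[lo]) / (centers[hi] - centers[lo]))
    inside <- pos > centers[1L] & pos < centers[k]
    w[!inside] <- 0
    lo[pos <= centers[1L]] <- 1L; hi[pos <= centers[1L]] <- 1L
    lo[pos >= centers[k]] <- k;   hi[pos >= centers[k]] <- k
    list(lo = lo, hi = hi, w = .clamp(w, 0, 1))
  }
  rc <- tileCoord(seq_len(nr), rCenters)
  cc <- tileCoord(seq_len(nc), cCenters)

  out <- matrix(0, nr, nc)
  lev <- v + 1L
  rowLo <- rc$lo[row(v)]; rowHi <- rc$hi[row(v)]; rowW <- rc$w[row(v)]
  colLo <- cc$lo[col(v)]; colHi <- cc$hi[col(v)]; colW <- cc$w[col(v)]
  pick <- function(ti, tj) maps[cbind(as.vector(lev), ti, tj)]
  out[] <- (1 - rowW) * (1 - colW) * pick(rowLo, colLo) +
           (1 - rowW) * colW       * pick(rowLo, colHi) +
           rowW       * (1 - colW) * pick(rowHi, colLo) +
           rowW       * colW       * pick(rowHi, colHi)
  matrix(as.integer(round(out)), nr, nc)
}
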