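# internal helpers shared across modules

# evaluate expr with a local RNG seed, restoring global RNG state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# min-max rescale to [0,1]; constant input maps to all zeros
.minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# symmetric (edge-inclusive) reflective padding by p pixels on all sides
.padReflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(p:1, 1:nr, nr:(nr - p + 1))
  cidx <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ridx, cidx, drop = FALSE]
}

# quantise intensities to integer levels 0..L-1
# grayLevels = NULL assumes values in [0,1]; otherwise values in 0..G-1
.quantizeLevels <- function(frame, levels, grayLevels = NULL) {
  if (is.null(grayLevels)) {
    if (min(frame) < 0 || max(frame) > 1)
      stop("frame values outside [0,1]; pass grayLevels for integer-mode data")
    k <- floor(frame * levels)
    k[k >= levels] <- levels - 1
  } else {
    k <- floor(frame * levels / grayLevels)
    k[k >= levels] <- levels - 1
  }
  storage.mode(k) <- "integer"
  k
}

# checked binary mask coercion (accepts logical or 0/1 numeric)
.asMask <- function(m, what = "mask") {
  if (is.logical(m)) { m <- m * 1L; }
  if (!all(m %in% c(0, 1))) stop(sprintf("%s must be binary (0/1)", what))
  storage.mode(m) <- "integer"
  m
}

# Otsu threshold of a continuous [0,1] map, returning the smallest
# observed value strictly above the Otsu cut (so mask = score >= value);
# a constant map yields +Inf (empty mask convention)
.otsuCut <- function(score) {
  rng <- range(score)
  if (rng[2] - rng[1] <= 0) return(Inf)
  t <- EBImage::otsu(EBImage::Image(score), range = c(0, 1), levels = 256L)
  above <- score[score > t]
  if (length(above) == 0L) return(Inf)
  min(above)
}

# count of 8-neighbours that are 1, computed by shifted sums
.neighborCount8 <- function(map) {
  p <- .padZero(map, 1L)
  nr <- nrow(map); nc <- ncol(map)
  rs <- 1L + seq_len(nr); cs <- 1L + seq_len(nc)
  p[rs - 1L, cs] + p[rs + 1L, cs] + p[rs, cs - 1L] + p[rs, cs + 1L] +
    p[rs - 1L, cs - 1L] + p[rs - 1L, cs + 1L] +
    p[rs + 1L, cs - 1L] + p[rs + 1L, cs + 1L]
}

.padZero <- function(m, p) {
  out <- matrix(0, nrow(m) + 2L * p, ncol(m) + 2L * p)
  out[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m
  out
}

# arc length of an ordered pixel path (unit/diagonal steps); single pixel -> 1
.arcLength <- function(path) {
  n <- nrow(path)
  if (n <= 1L) return(1)
  sum(sqrt(rowSums((path[-1L, , drop = FALSE] -
                    path[-n, , drop = FALSE])^2)))
}

# euclidean distance from every pixel to the nearest 1-pixel of `map`
.distanceToSet <- function(map) {
  if (sum(map) == 0L) return(matrix(Inf, nrow(map), ncol(map)))
  d <- EBImage::distmap(1 - map, metric = "euclidean")
  matrix(as.numeric(d), nrow(map), ncol(map))
}
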