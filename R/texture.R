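# The three per-frame texture descriptors and their fusion into the
# combined vessel-evidence map, plus the sequence-level two-channel model
# input built from a minimum intensity projection. All descriptors operate
# on vessel-bright frames; borders are handled by symmetric reflective
# padding so the dark image border cannot pollute the statistics.

.checkWindow <- function(window, frame) {
  if (window %% 2 == 0 || window < 3 || window > min(dim(frame)))
    stop("window must be odd, >= 3 and no larger than the frame")
}

#' Local contrast: windowed intensity variance
#'
#' For each pixel, the population variance of intensities in the w x w
#' neighborhood: C(x,y) = (1/N) * sum over the window of (I - mu)^2 with
#' N = w^2 (no square root, in squared-intensity units). Zero on constant
#' neighborhoods. \code{sqrt = TRUE} returns the windowed standard
#' deviation instead.
#'
#' @param frame numeric matrix (vessel-bright)
#' @param window odd window side length (default 5)
#' @param sqrt return the square root of the variance
#' @return non-negative matrix of the same shape
#' @export
localContrast <- function(frame, window = 5, sqrt = FALSE) {
  .checkWindow(window, frame)
  out <- localContrastC(frame, as.integer(window))
  if (sqrt) base::sqrt(out) else out
}

#' Local entropy: windowed Shannon entropy in bits
#'
#' The frame is quantised to \code{levels} gray levels, and for each pixel
#' H(x,y) = -sum_k p_k * log2(p_k + eps) over the within-window level
#' frequencies p_k. The small constant eps is added inside the logarithm,
#' so a constant window yields -log2(1 + eps), about -3.2e-16, rather than
#' exactly zero.
#'
#' @param frame numeric matrix (vessel-bright); values in [0,1] unless
#'   \code{grayLevels} identifies integer-mode data in 0..G-1
#' @param window odd window side length (default 5)
#' @param levels histogram bin count L (default 256)
#' @param eps additive constant inside the logarithm (default 2^-52)
#' @param grayLevels gray-level count of integer-mode input, or NULL
#' @return matrix of entropies in bits, bounded by log2(min(L, window^2))
#' @export
localEntropy <- function(frame, window = 5, levels = 256,
                         eps = 2^-52, grayLevels = NULL) {
  .checkWindow(window, frame)
  if (levels < 2) stop("levels must be >= 2")
  q <- .quantizeLevels(frame, levels, grayLevels)
  localEntropyC(q, as.integer(window), as.integer(levels), eps)
}

#' Brightness threshold: per-frame percentile cut
#'
#' T is the smallest intensity at which the frame's empirical cumulative
#' distribution reaches q (the whole frame, no sub-regions), and the
#' bright mask selects strictly brighter pixels: B = 1 iff I > T.
#' Consequently at most a (1-q) fraction of pixels is selected.
#'
#' @param frame numeric matrix (vessel-bright)
#' @param q cumulative probability in (0,1); the default 0.85 keeps the
#'   brightest 15 percent
#' @return list with elements \code{threshold} (T) and \code{mask} (B)
#' @export
brightnessThreshold <- function(frame, q = 0.85) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  v <- sort(as.vector(frame))
  T <- v[ceiling(q * length(v))]
  list(threshold = T, mask = .asMask((frame > T) * 1L))
}

#' Compute the three texture descriptors of one frame
#'
#' @param frame numeric vessel-bright matrix in [0,1] (use
#'   \code{\link{normalizeFrame}} first for integer-mode data)
#' @param window odd window side length for contrast and entropy
#' @param levels entropy histogram bin count
#' @param q brightness percentile
#' @param eps entropy logarithm constant
#' @return a \code{\link{FeatureMaps}} object
#' @export
computeFeatureMaps <- function(frame, window = 5, levels = 256, q = 0.85,
                               eps = 2^-52) {
  if (min(frame) < 0 || max(frame) > 1)
    stop("frame must be normalized to [0,1]")
  bt <- brightnessThreshold(frame, q)
  new("FeatureMaps",
      contrast = localContrast(frame, window),
      entropy = localEntropy(frame, window, levels, eps),
      threshold = bt$threshold, brightMask = bt$mask,
      window = window, levels = levels, eps = eps)
}

#' Fuse the texture descriptors into the combined mask
#'
#' The contrast and entropy maps are min-max normalized per frame and
#' combined convexly with the binary bright mask:
#' F = w_c * C^ + w_e * H^ + w_b * B. The binary mask M selects pixels
#' with F at or above the fusion threshold (Otsu's threshold of F by
#' default, or a fixed value). An optional pre-binarisation of the
#' normalized entropy map at \code{entropyCut} is available (off by
#' default).
#'
#' @param feature a \code{\link{FeatureMaps}} object
#' @param weights non-negative weights (contrast, entropy, brightness);
#'   rescaled to sum to one
#' @param threshold \code{"otsu"} or a fixed numeric threshold on F
#' @param entropyCut optional cut in [0,1] applied to the normalized
#'   entropy map before fusion, or NULL
#' @return a \code{\link{CombinedMask}}
#' @export
fuseFeatures <- function(feature, weights = c(1, 1, 1) / 3,
                         threshold = "otsu", entropyCut = NULL) {
  if (length(weights) != 3L || any(weights < 0) || sum(weights) == 0)
    stop("weights must be three non-negative values with positive sum")
  w <- weights / sum(weights)
  Chat <- .minmax01(feature@contrast)
  Hhat <- .minmax01(feature@entropy)
  if (!is.null(entropyCut)) Hhat <- (Hhat >= entropyCut) * 1
  F <- w[1] * Chat + w[2] * Hhat + w[3] * feature@brightMask
  F <- .clamp(F, 0, 1)
  if (identical(threshold, "otsu")) {
    cut <- .otsuCut(F); method <- "otsu"
  } else {
    cut <- as.numeric(threshold); method <- "fixed"
  }
  new("CombinedMask", score = F, mask = .asMask((F >= cut) * 1L),
      weights = w, fusionThreshold = cut, thresholdMethod = method)
}

#' Minimum intensity projection of a sequence
#'
#' Pixel-wise minimum across all frames; on a raw vessel-dark stack this
#' keeps each vessel pixel at its darkest (most contrast-filled) value.
#'
#' @param seq a \code{DSASequence} with at least one frame
#' @return matrix of the same frame shape
#' @export
minIntensityProjection <- function(seq) {
  if (nFrames(seq) == 0L) stop("empty input: sequence has no frames")
  apply(seq@frames, c(1, 2), min)
}

# projection frame in the vessel-bright convention: MinIP of the raw dark
# stack then inverted, equivalently a maximum projection of bright frames
.brightProjection <- function(seq) {
  top <- if (seq@mode == "integer") seq@grayLevels - 1 else 1
  if (seq@polarity == "vessel_dark") top - minIntensityProjection(seq)
  else apply(seq@frames, c(1, 2), max)
}

#' Build the two-channel sequence-level model input
#'
#' Channel \code{minip} is the combined score of the vessel-bright
#' converted minimum intensity projection; channel \code{sum} is the
#' pixel-wise sum of the per-frame combined scores, min-max renormalized
#' to [0,1] so the channel is stable against frame count.
#'
#' @param seq a \code{DSASequence} of known polarity
#' @param window,levels,q,eps descriptor parameters, see
#'   \code{\link{computeFeatureMaps}}
#' @param weights,threshold,entropyCut fusion parameters, see
#'   \code{\link{fuseFeatures}}
#' @return a \code{\link{ModelInput}}
#' @export
buildModelInput <- function(seq, window = 5, levels = 256, q = 0.85,
                            eps = 2^-52, weights = c(1, 1, 1) / 3,
                            threshold = "otsu", entropyCut = NULL) {
  seqB <- toVesselBright(seq)
  scoreOf <- function(frame) {
    fm <- computeFeatureMaps(normalizeFrame(frame), window, levels, q, eps)
    combinedScore(fuseFeatures(fm, weights, threshold, entropyCut))
  }
  total <- 0
  for (i in seq_len(nFrames(seqB))) total <- total + scoreOf(getFrame(seqB, i))
  new("ModelInput",
      minip = scoreOf(.brightProjection(seq)),
      sum = .minmax01(total))
}

#' Preprocess a sequence: per-frame combined masks plus the model input
#'
#' @inheritParams buildModelInput
#' @return list with \code{combined} (per-frame \code{CombinedMask}
#'   objects) and \code{modelInput} (a \code{\link{ModelInput}})
#' @export
preprocessSequence <- function(seq, window = 5, levels = 256, q = 0.85,
                               eps = 2^-52, weights = c(1, 1, 1) / 3,
                               threshold = "otsu", entropyCut = NULL) {
  seqB <- toVesselBright(seq)
  combined <- lapply(seq_len(nFrames(seqB)), function(i) {
    fm <- computeFeatureMaps(normalizeFrame(getFrame(seqB, i)),
                             window, levels, q, eps)
    fuseFeatures(fm, weights, threshold, entropyCut)
  })
  total <- Reduce(`+`, lapply(combined, combinedScore))
  fmP <- computeFeatureMaps(normalizeFrame(.brightProjection(seq)),
                            window, levels, q, eps)
  mi <- new("ModelInput",
            minip = combinedScore(fuseFeatures(fmP, weights, threshold,
                                               entropyCut)),
            sum = .minmax01(total))
  list(combined = combined, modelInput = mi)
}
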