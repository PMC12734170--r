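#' @import methods
#' @importFrom stats rnorm runif rbinom sd qnorm
#' @importFrom utils write.csv head tail
#' @useDynLib vesseltex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.POLARITIES <- c("vessel_dark", "vessel_bright")
.VIEWS <- c("anteroposterior", "lateral", "unknown")
.MODES <- c("integer", "normalized")

#' DSASequence: an ordered stack of grayscale angiographic frames
#'
#' Frames are stored as a numeric height x width x time array. In
#' \code{integer} mode pixel values lie in \code{0..grayLevels-1}; in
#' \code{normalized} mode they lie in \code{[0,1]}. The polarity records
#' whether contrast-filled vessels are darker or brighter than background;
#' raw subtraction angiograms are \code{vessel_dark}, and all texture
#' descriptors operate on \code{vessel_bright} frames (see
#' \code{\link{toVesselBright}}).
#'
#' @slot frames numeric array, height x width x n_frames
#' @slot frameRate numeric, frames per second (metadata; default 4)
#' @slot polarity \code{"vessel_dark"} or \code{"vessel_bright"}
#' @slot view acquisition view (metadata)
#' @slot grayLevels total number of gray levels G (integer mode)
#' @slot mode \code{"integer"} or \code{"normalized"}
#' @export
setClass("DSASequence", representation(
  frames = "array", frameRate = "numeric", polarity = "character",
  view = "character", grayLevels = "numeric", mode = "character"
))

setValidity("DSASequence", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) return("frames must be a 3-D array")
  if (dim(f)[3] < 1L) return("sequence must contain at least one frame")
  if (!object@polarity %in% .POLARITIES)
    return("polarity must be 'vessel_dark' or 'vessel_bright'")
  if (!object@view %in% .VIEWS)
    return("unknown view")
  if (!object@mode %in% .MODES)
    return("mode must be 'integer' or 'normalized'")
  if (object@mode == "integer") {
    if (object@grayLevels < 2) return("grayLevels must be >= 2")
    if (min(f) < 0 || max(f) > object@grayLevels - 1)
      return("integer-mode intensities must lie in [0, G-1]")
  } else {
    if (min(f) < 0 || max(f) > 1)
      return("normalized intensities must lie in [0, 1]")
  }
  TRUE
})

#' @describeIn DSASequence construct a sequence from a list of frames
#' @param frames list of numeric matrices (all same shape) or a 3-D array
#' @param polarity vessel polarity of the frames
#' @param frameRate acquisition frame rate in fps
#' @param view acquisition view
#' @param grayLevels gray-level count G for integer-mode data
#' @param mode \code{"integer"} or \code{"normalized"}
#' @export
DSASequence <- function(frames, polarity = "vessel_dark", frameRate = 4,
                        view = "unknown", grayLevels = 256,
                        mode = "integer") {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("empty input: no frames")
    d <- dim(frames[[1L]])
    for (f in frames) if (!identical(dim(f), d))
      stop("shape mismatch: frames differ in dimensions")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  storage.mode(frames) <- "double"
  new("DSASequence", frames = frames, frameRate = frameRate,
      polarity = polarity, view = view, grayLevels = grayLevels,
      mode = mode)
}

setMethod("show", "DSASequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("DSASequence: %d frame(s) of %d x %d, %s mode (G = %d), %s, %.3g fps\n",
              d[3], d[1], d[2], object@mode, as.integer(object@grayLevels),
              object@polarity, object@frameRate))
})

#' Number of frames in a sequence
#' @param seq a \code{DSASequence}
#' @export
nFrames <- function(seq) dim(seq@frames)[3]

#' Extract one frame as a matrix
#' @param seq a \code{DSASequence}
#' @param i frame index (1-based, temporal order)
#' @export
getFrame <- function(seq, i) seq@frames[, , i]

#' Vessel polarity of a sequence
#' @param seq a \code{DSASequence}
#' @export
polarity <- function(seq) seq@polarity

#' Gray-level count of a sequence
#' @param seq a \code{DSASequence}
#' @export
grayLevels <- function(seq) seq@grayLevels

#' FeatureMaps: the three per-frame texture descriptors
#'
#' @slot contrast windowed-variance local contrast map (>= 0)
#' @slot entropy windowed Shannon entropy map in bits
#' @slot threshold the brightness percentile cut T (scalar intensity)
#' @slot brightMask binary matrix, 1 where intensity > T
#' @slot window odd window side length
#' @slot levels histogram bin count used for the entropy map
#' @slot eps additive constant inside the entropy logarithm
#' @export
setClass("FeatureMaps", representation(
  contrast = "matrix", entropy = "matrix", threshold = "numeric",
  brightMask = "matrix", window = "numeric", levels = "numeric",
  eps = "numeric"
))

setValidity("FeatureMaps", function(object) {
  if (!identical(dim(object@contrast), dim(object@entropy)) ||
      !identical(dim(object@contrast), dim(object@brightMask)))
    return("feature maps must share one shape")
  if (min(object@contrast) < 0) return("contrast map must be non-negative")
  TRUE
})

setMethod("show", "FeatureMaps", function(object) {
  d <- dim(object@contrast)
  cat(sprintf("FeatureMaps: %d x %d, window %d, %d entropy levels, T = %.4g, |B| = %d\n",
              d[1], d[2], as.integer(object@window),
              as.integer(object@levels), object@threshold,
              sum(object@brightMask)))
})

#' CombinedMask: fused continuous and binary vessel evidence
#'
#' @slot score fused score F in [0,1]
#' @slot mask binary mask M, 1 where F >= fusion threshold
#' @slot weights the convex weights (contrast, entropy, brightness)
#' @slot fusionThreshold the realised threshold value on F
#' @slot thresholdMethod \code{"otsu"} or \code{"fixed"}
#' @export
setClass("CombinedMask", representation(
  score = "matrix", mask = "matrix", weights = "numeric",
  fusionThreshold = "numeric", thresholdMethod = "character"
))

setValidity("CombinedMask", function(object) {
  if (min(object@score) < -1e-12 || max(object@score) > 1 + 1e-12)
    return("fused score must lie in [0,1]")
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  TRUE
})

setMethod("show", "CombinedMask", function(object) {
  d <- dim(object@score)
  cat(sprintf("CombinedMask: %d x %d, weights (%.3g, %.3g, %.3g), %s threshold %.4g, %d vessel px\n",
              d[1], d[2], object@weights[1], object@weights[2],
              object@weights[3], object@thresholdMethod,
              object@fusionThreshold, sum(object@mask)))
})

#' Accessors for CombinedMask
#' @param x a \code{CombinedMask}
#' @export
combinedScore <- function(x) x@score

#' @rdname combinedScore
#' @export
combinedMask <- function(x) x@mask

#' ModelInput: the two-channel sequence-level representation
#'
#' Channel 1 is the combined score of the (vessel-bright) minimum intensity
#' projection; channel 2 is the renormalised pixel-wise sum of the per-frame
#' combined scores.
#'
#' @slot minip combined score of the MinIP frame, in [0,1]
#' @slot sum renormalised sum of per-frame scores, in [0,1]
#' @export
setClass("ModelInput", representation(minip = "matrix", sum = "matrix"))

setValidity("ModelInput", function(object) {
  if (!identical(dim(object@minip), dim(object@sum)))
    return("channels must share one shape")
  rng <- range(object@minip, object@sum)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    return("channels must lie in [0,1]")
  TRUE
})

setMethod("show", "ModelInput", function(object) {
  d <- dim(object@minip)
  cat(sprintf("ModelInput: 2 channels (minip, sum), %d x %d\n", d[1], d[2]))
})

#' ConfusionCounts: pixel tallies of a predicted vs reference mask pair
#' @slot tp,tn,fp,fn non-negative pixel counts
#' @export
setClass("ConfusionCounts", representation(
  tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d, TN %d, FP %d, FN %d\n",
              object@tp, object@tn, object@fp, object@fn))
})

#' Skeleton: 1-pixel-wide 8-connected centerline of a binary mask
#' @slot map binary matrix, 1 on the centerline
#' @export
setClass("Skeleton", representation(map = "matrix"))

setValidity("Skeleton", function(object) {
  if (!all(object@map %in% c(0, 1))) return("skeleton map must be binary")
  TRUE
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d centerline pixel(s) on a %d x %d grid\n",
              sum(object@map), nrow(object@map), ncol(object@map)))
})

#' Pixel coordinates of a skeleton (n x 2 matrix of row, col)
#' @param skel a \code{Skeleton}
#' @export
skeletonPixels <- function(skel) which(skel@map == 1, arr.ind = TRUE)

#' SegmentSet: centerline decomposed into junction-to-terminal segments
#'
#' @slot paths list of ordered n x 2 (row, col) pixel paths
#' @slot junctions m x 2 matrix of junction pixels (degree >= 3)
#' @slot endpoints m x 2 matrix of endpoint pixels (degree == 1)
#' @slot lengths per-segment arc length (unit steps 1, diagonal sqrt(2);
#'   a one-pixel segment has arc length 1)
#' @export
setClass("SegmentSet", representation(
  paths = "list", junctions = "matrix", endpoints = "matrix",
  lengths = "numeric"
))

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segment(s), %d junction(s), %d endpoint(s), total arc length %.2f px\n",
              length(object@paths), nrow(object@junctions),
              nrow(object@endpoints), sum(object@lengths)))
})

#' Number of segments
#' @param x a \code{SegmentSet}
#' @export
nSegments <- function(x) length(x@paths)

#' VCResult: the Vessel Connectivity metric and its per-segment terms
#'
#' @slot vc mean connectivity error over ground-truth segments (pixels;
#'   lower is better, 0 iff every centerline pixel matched at distance 0)
#' @slot perSegmentCE per-segment connectivity errors
#' @slot matchedFraction fraction of centerline points matched within rMatch
#' @slot rMatch matching radius in pixels
#' @export
setClass("VCResult", representation(
  vc = "numeric", perSegmentCE = "numeric", matchedFraction = "numeric",
  rMatch = "numeric"
))

setMethod("show", "VCResult", function(object) {
  cat(sprintf("Vessel Connectivity: VC = %.4f over %d segment(s), matched fraction %.3f (r_match = %.3g px)\n",
              object@vc, length(object@perSegmentCE),
              object@matchedFraction, object@rMatch))
})

#' VesselTree: phantom ground-truth centerline tree
#'
#' @slot nodes n x 2 matrix of (row, col) node positions
#' @slot edges data.frame with columns from, to (node indices), radius
#'   (pixels) and depth (0 = trunk)
#' @slot arrival per-node bolus arrival time in seconds (geodesic path
#'   length from the root divided by the flow speed)
#' @slot root index of the root node (on the image border)
#' @slot size image size (rows, cols) the tree was generated for
#' @export
setClass("VesselTree", representation(
  nodes = "matrix", edges = "data.frame", arrival = "numeric",
  root = "numeric", size = "numeric"
))

setValidity("VesselTree", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    r <- e$radius[match(e$from, e$to)]
    ok <- is.na(r) | e$radius <= r + 1e-9
    if (!all(ok)) return("child radius must not exceed parent radius")
  }
  a <- object@arrival[object@edges$to] - object@arrival[object@edges$from]
  if (length(a) && min(a) < -1e-9)
    return("arrival times must be non-decreasing from root to leaves")
  TRUE
})

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d node(s), %d edge(s), max depth %d, arrival span %.2f s\n",
              nrow(object@nodes), nrow(object@edges),
              if (nrow(object@edges)) max(object@edges$depth) else 0L,
              max(object@arrival)))
})

#' PhantomConfig: parameters of the synthetic angiography phantom
#'
#' Defaults emulate the reference acquisition conditions: 800 x 800 frames,
#' 4 fps, sequences of 4 to 14 frames (drawn per seed when \code{nFrames}
#' is NA). Geometry and photometry defaults are documented in the methods
#' vignette.
#'
#' @slot size image size in pixels (rows, cols)
#' @slot nFrames frame count; NA draws uniformly from 4..14 per seed
#' @slot frameRate frames per second
#' @slot depth bifurcation depth of the vessel tree
#' @slot angleRange branch half-angle range in degrees
#' @slot radiusDecay per-depth multiplicative radius decay
#' @slot rootRadius trunk radius in pixels (NA scales with image size)
#' @slot branchLength trunk length in pixels (NA scales with image size)
#' @slot lengthDecay per-depth multiplicative length decay
#' @slot flowSpeed contrast bolus speed along the centerline (px/s)
#' @slot backgroundLevel mean background intensity (vessel-dark frames)
#' @slot backgroundAmplitude amplitude of the smooth background field
#' @slot boneCount number of bone-like dark band artifacts
#' @slot boneDepth intensity depression of bone bands
#' @slot vesselDepth intensity depression of filled vessels
#' @slot noiseSd additive Gaussian noise sd (on the [0,1] scale)
#' @export
setClass("PhantomConfig", representation(
  size = "numeric", nFrames = "numeric", frameRate = "numeric",
  depth = "numeric", angleRange = "numeric", radiusDecay = "numeric",
  rootRadius = "numeric", branchLength = "numeric", lengthDecay = "numeric",
  flowSpeed = "numeric", backgroundLevel = "numeric",
  backgroundAmplitude = "numeric", boneCount = "numeric",
  boneDepth = "numeric", vesselDepth = "numeric", noiseSd = "numeric"
))

#' @describeIn PhantomConfig constructor with study-condition defaults
#' @param size,nFrames,frameRate,depth,angleRange,radiusDecay,rootRadius
#'   see slots
#' @param branchLength,lengthDecay,flowSpeed,backgroundLevel see slots
#' @param backgroundAmplitude,boneCount,boneDepth,vesselDepth,noiseSd
#'   see slots
#' @export
phantomConfig <- function(size = c(800, 800), nFrames = NA_real_,
                          frameRate = 4, depth = 6,
                          angleRange = c(18, 38), radiusDecay = 0.78,
                          rootRadius = NA_real_, branchLength = NA_real_,
                          lengthDecay = 0.75, flowSpeed = 300,
                          backgroundLevel = 0.55,
                          backgroundAmplitude = 0.18, boneCount = 2,
                          boneDepth = 0.18, vesselDepth = 0.28,
                          noiseSd = 5 / 255) {
  if (length(size) == 1L) size <- c(size, size)
  if (is.na(rootRadius)) rootRadius <- max(3, round(min(size) / 64))
  if (is.na(branchLength)) branchLength <- 0.30 * min(size)
  stopifnot(all(size >= 32), frameRate > 0, depth >= 0, radiusDecay > 0,
            radiusDecay <= 1, rootRadius >= 1, branchLength > 0,
            lengthDecay > 0, flowSpeed > 0, noiseSd >= 0)
  new("PhantomConfig", size = size, nFrames = nFrames,
      frameRate = frameRate, depth = depth, angleRange = angleRange,
      radiusDecay = radiusDecay, rootRadius = rootRadius,
      branchLength = branchLength, lengthDecay = lengthDecay,
      flowSpeed = flowSpeed, backgroundLevel = backgroundLevel,
      backgroundAmplitude = backgroundAmplitude, boneCount = boneCount,
      boneDepth = boneDepth, vesselDepth = vesselDepth, noiseSd = noiseSd)
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d px, %s frame(s) at %g fps, depth %d tree, flow %g px/s, noise sd %.4g\n",
              object@size[1], object@size[2],
              if (is.na(object@nFrames)) "4-14" else as.character(object@nFrames),
              object@frameRate, as.integer(object@depth), object@flowSpeed,
              object@noiseSd))
})

#' PatchGrid: sliding-window patch origins over a source image
#'
#' @slot size patch side length in pixels
#' @slot stride sliding stride in pixels
#' @slot origins k x 2 matrix of (row, col) patch origins (1-based)
#' @slot sourceDim source image size (rows, cols)
#' @export
setClass("PatchGrid", representation(
  size = "numeric", stride = "numeric", origins = "matrix",
  sourceDim = "numeric"
))

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patch(es) of %d px, stride %d, source %d x %d\n",
              nrow(object@origins), as.integer(object@size),
              as.integer(object@stride), object@sourceDim[1],
              object@sourceDim[2]))
})

#' UNetSpec: a verifiable layer-by-layer network description
#'
#' @slot layers data.frame with one row per parameterised layer (name,
#'   type, kernel, in/out channels, parameter count)
#' @slot paramCount total trainable parameter count
#' @slot depth number of encoder resolution levels
#' @slot baseChannels feature maps at the first level
#' @slot inChannels,outChannels network input/output channels
#' @export
setClass("UNetSpec", representation(
  layers = "data.frame", paramCount = "numeric", depth = "numeric",
  baseChannels = "numeric", inChannels = "numeric", outChannels = "numeric"
))

setMethod("show", "UNetSpec", function(object) {
  cat(sprintf("UNetSpec: depth %d, base %d channels, %d -> %d channels, %s trainable parameters (%d layers)\n",
              as.integer(object@depth), as.integer(object@baseChannels),
              as.integer(object@inChannels), as.integer(object@outChannels),
              format(object@paramCount, big.mark = ","),
              nrow(object@layers)))
})

#' AugmentationPolicy: the five-operator training augmentation policy
#'
#' Each operator (rotation, horizontal flip, vertical flip, contrast
#' jitter, Gaussian noise) fires independently with probability
#' \code{prob}. Geometric operators are applied identically to the image
#' and its label mask; photometric operators touch the image only.
#'
#' @slot rotationRange rotation angle range in degrees
#' @slot contrastRange relative contrast-jitter range
#' @slot noiseSdRange Gaussian noise sd range (on the [0,1] scale)
#' @slot prob per-operator firing probability
#' @export
setClass("AugmentationPolicy", representation(
  rotationRange = "numeric", contrastRange = "numeric",
  noiseSdRange = "numeric", prob = "numeric"
))

#' @describeIn AugmentationPolicy constructor with the default policy
#' @param rotationRange,contrastRange,noiseSdRange,prob see slots
#' @export
augmentationPolicy <- function(rotationRange = c(-15, 15),
                               contrastRange = c(-0.2, 0.2),
                               noiseSdRange = c(0, 0.05), prob = 0.5) {
  new("AugmentationPolicy", rotationRange = rotationRange,
      contrastRange = contrastRange, noiseSdRange = noiseSdRange,
      prob = prob)
}

setMethod("show", "AugmentationPolicy", function(object) {
  cat(sprintf("AugmentationPolicy: 5 operators at p = %.2g (rotation %g..%g deg, contrast %g..%g, noise sd %g..%g)\n",
              object@prob, object@rotationRange[1], object@rotationRange[2],
              object@contrastRange[1], object@contrastRange[2],
              object@noiseSdRange[1], object@noiseSdRange[2]))
})
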