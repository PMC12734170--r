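# Patch tiling and stitching per the training protocol (256 px patches
# slid by 20 px, with a forced final origin so borders are covered), a
# verifiable U-Net architecture specification with an analytic parameter
# count, the five-operator augmentation policy, sequence-level data
# splits, and a classical threshold segmenter that makes the full
# preprocess -> segment -> evaluate loop executable at desk scale.

.axisOrigins <- function(dimLen, size, stride) {
  last <- dimLen - size + 1L
  o <- seq.int(1L, last, by = stride)
  if (o[length(o)] != last) o <- c(o, last)
  o
}

#' Tile an image into overlapping patches
#'
#' Patch origins advance by \code{stride} along each axis, with a final
#' origin forced at \code{dim - size} when the stride does not land there,
#' so every source pixel is covered and all patches lie fully inside the
#' image. An 800 x 800 frame at size 256 / stride 20 yields 29 origins per
#' axis, 841 patches.
#'
#' @param image matrix or height x width x channels array, at least
#'   \code{size} pixels in both spatial dimensions
#' @param size patch side length (default 256)
#' @param stride sliding stride in pixels (default 20)
#' @return list with \code{patches} (list, in row-major origin order) and
#'   \code{grid} (a \code{\link{PatchGrid}})
#' @export
tilePatches <- function(image, size = 256, stride = 20) {
  d <- dim(image)
  if (d[1] < size || d[2] < size) stop("image smaller than patch size")
  ro <- .axisOrigins(d[1], size, stride)
  co <- .axisOrigins(d[2], size, stride)
  origins <- cbind(rep(ro, times = length(co)),
                   rep(co, each = length(ro)))
  patches <- lapply(seq_len(nrow(origins)), function(k) {
    r <- origins[k, 1L]; c <- origins[k, 2L]
    if (length(d) == 3L) image[r:(r + size - 1L), c:(c + size - 1L), , drop = FALSE]
    else image[r:(r + size - 1L), c:(c + size - 1L)]
  })
  list(patches = patches,
       grid = new("PatchGrid", size = size, stride = stride,
                  origins = origins, sourceDim = d[1:2]))
}

#' Stitch patch outputs back into a full map
#'
#' Overlapping patch outputs are averaged per pixel, so stitching the
#' tiles of an image reproduces it exactly.
#'
#' @param patches list of patch-shaped matrices, one per grid origin
#' @param grid the \code{\link{PatchGrid}} from \code{\link{tilePatches}}
#' @return matrix of the grid's source dimensions
#' @export
stitchPatches <- function(patches, grid) {
  if (length(patches) != nrow(grid@origins))
    stop("patch count does not match the grid")
  s <- grid@size
  acc <- matrix(0, grid@sourceDim[1], grid@sourceDim[2])
  cnt <- matrix(0, grid@sourceDim[1], grid@sourceDim[2])
  for (k in seq_along(patches)) {
    r <- grid@origins[k, 1L]; c <- grid@origins[k, 2L]
    rows <- r:(r + s - 1L); cols <- c:(c + s - 1L)
    acc[rows, cols] <- acc[rows, cols] + patches[[k]]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  acc / cnt
}

.convParams <- function(k, cin, cout) k * k * cin * cout + cout

#' Build the segmentation network specification
#'
#' A U-Net with \code{depth} encoder resolution levels starting at
#' \code{base} feature maps and doubling per level, a bottleneck at twice
#' the deepest encoder width, and a mirrored decoder: two 3 x 3
#' convolutions per level (batch normalization in the encoder, instance
#' normalization in the decoder, as described), 2 x 2 max pooling, 2 x 2
#' transposed-convolution upsampling with skip concatenations, and a
#' 1 x 1 softmax head. The trainable parameter count is computed
#' analytically from the layer listing; the default configuration lands
#' near nine million parameters.
#'
#' @param depth encoder resolution levels (default 4)
#' @param base feature maps at the first level (default 32)
#' @param inChannels network input channels (default 2: the two-channel
#'   model input)
#' @param outChannels output channels (default 2, softmax over
#'   vessel/background for a categorical cross-entropy loss)
#' @return a \code{\link{UNetSpec}}
#' @export
buildUNetSpec <- function(depth = 4, base = 32, inChannels = 2,
                          outChannels = 2) {
  stopifnot(depth >= 1, base >= 1)
  layers <- list()
  add <- function(name, type, kernel, cin, cout, norm = "none") {
    p <- switch(type,
                conv = .convParams(kernel, cin, cout),
                transpose = kernel * kernel * cin * cout + cout,
                pool = 0)
    np <- if (norm == "none") 0 else 2 * cout
    layers[[length(layers) + 1L]] <<- data.frame(
      name = name, type = type, kernel = kernel, inChannels = cin,
      outChannels = cout, normalization = norm,
      params = p + np, stringsAsFactors = FALSE)
  }
  ch <- base * 2^(seq_len(depth) - 1L)
  cin <- inChannels
  for (l in seq_len(depth)) {
    add(sprintf("enc%d_conv1", l), "conv", 3, cin, ch[l], "batch")
    add(sprintf("enc%d_conv2", l), "conv", 3, ch[l], ch[l], "batch")
    add(sprintf("enc%d_pool", l), "pool", 2, ch[l], ch[l])
    cin <- ch[l]
  }
  bott <- ch[depth] * 2L
  add("bottleneck_conv1", "conv", 3, ch[depth], bott, "batch")
  add("bottleneck_conv2", "conv", 3, bott, bott, "batch")
  cin <- bott
  for (l in rev(seq_len(depth))) {
    add(sprintf("dec%d_up", l), "transpose", 2, cin, ch[l])
    add(sprintf("dec%d_conv1", l), "conv", 3, 2L * ch[l], ch[l], "instance")
    add(sprintf("dec%d_conv2", l), "conv", 3, ch[l], ch[l], "instance")
    cin <- ch[l]
  }
  add("head", "conv", 1, base, outChannels)
  tab <- do.call(rbind, layers)
  new("UNetSpec", layers = tab, paramCount = sum(tab$params),
      depth = depth, baseChannels = base, inChannels = inChannels,
      outChannels = outChannels)
}

# inverse-mapping rotation about the image center; outside pixels -> 0
.rotateImage <- function(img, angleDeg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angleDeg * pi / 180
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  srcR <- cos(th) * rr + sin(th) * cc + cy
  srcC <- -sin(th) * rr + cos(th) * cc + cx
  out <- matrix(0, h, w)
  if (interp == "nearest") {
    ri <- round(srcR); ci <- round(srcC)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(srcR); c0 <- floor(srcC)
    fr <- srcR - r0; fc <- srcC - c0
    ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
    g <- function(dr, dc) img[cbind(r0[ok] + dr, c0[ok] + dc)]
    out[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * g(0L, 0L) +
               (1 - fr[ok]) * fc[ok]       * g(0L, 1L) +
               fr[ok]       * (1 - fc[ok]) * g(1L, 0L) +
               fr[ok]       * fc[ok]       * g(1L, 1L)
  }
  out
}

#' Apply the five-operator augmentation policy to a patch and its mask
#'
#' Rotation, horizontal flip, vertical flip, contrast jitter and Gaussian
#' noise each fire independently with the policy's probability.
#' Geometric transforms are applied identically to the patch (bilinear)
#' and the mask (nearest neighbour, so it stays binary); photometric
#' transforms touch the patch only. Deterministic per seed.
#'
#' @param patch numeric matrix in [0,1]
#' @param mask binary matrix of the same shape
#' @param policy an \code{\link{AugmentationPolicy}}
#' @param seed integer seed
#' @param force optional logical vector of length 5 overriding the random
#'   firing decisions (rotation, hflip, vflip, contrast, noise)
#' @return list with \code{patch}, \code{mask} and \code{applied}
#'   (named logical vector of which operators fired)
#' @export
augmentPatch <- function(patch, mask, policy = augmentationPolicy(),
                         seed = 1, force = NULL) {
  if (!identical(dim(patch), dim(mask)))
    stop("patch and mask must share one shape")
  mask <- .asMask(mask)
  .withSeed(seed, {
    fire <- if (is.null(force)) runif(5) < policy@prob else as.logical(force)
    names(fire) <- c("rotation", "hflip", "vflip", "contrast", "noise")
    if (fire["rotation"]) {
      ang <- runif(1, policy@rotationRange[1], policy@rotationRange[2])
      patch <- .rotateImage(patch, ang, "bilinear")
      mask <- .rotateImage(mask, ang, "nearest")
    }
    if (fire["hflip"]) { patch <- patch[, ncol(patch):1]; mask <- mask[, ncol(mask):1] }
    if (fire["vflip"]) { patch <- patch[nrow(patch):1, ]; mask <- mask[nrow(mask):1, ] }
    if (fire["contrast"]) {
      f <- 1 + runif(1, policy@contrastRange[1], policy@contrastRange[2])
      mu <- mean(patch)
      patch <- .clamp(mu + (patch - mu) * f, 0, 1)
    }
    if (fire["noise"]) {
      sdv <- runif(1, policy@noiseSdRange[1], policy@noiseSdRange[2])
      patch <- .clamp(patch + rnorm(length(patch), 0, sdv), 0, 1)
    }
    list(patch = patch, mask = .asMask(mask), applied = fire)
  })
}

#' Sequence-level train/validation/test split
#'
#' Shuffles sequence identifiers and assigns floor(0.7 n) to training,
#' floor(0.1 n) to validation and the remainder to test, so frames from
#' one sequence can never appear in more than one subset.
#'
#' @param n number of sequences
#' @param seed integer seed
#' @param ratios train/validation proportions (test takes the rest)
#' @return list with integer vectors \code{train}, \code{validation},
#'   \code{test}
#' @export
splitSequences <- function(n, seed = 1, ratios = c(0.7, 0.1)) {
  stopifnot(n >= 1, length(ratios) == 2, sum(ratios) < 1)
  .withSeed(seed, {
    idx <- sample.int(n)
    nTr <- floor(ratios[1] * n); nVa <- floor(ratios[2] * n)
    list(train = sort(idx[seq_len(nTr)]),
         validation = sort(idx[nTr + seq_len(nVa)]),
         test = sort(idx[setdiff(seq_len(n), seq_len(nTr + nVa))]))
  })
}

#' Threshold segmenter over the two-channel model input
#'
#' Averages the two channels and binarises at Otsu's threshold (or a
#' fixed value); the classical stand-in that makes the full
#' preprocess -> segment -> evaluate loop executable without a trained
#' network.
#'
#' @param input a \code{\link{ModelInput}}
#' @param threshold \code{"otsu"} or a fixed numeric threshold
#' @return binary mask matrix
#' @export
thresholdSegmenter <- function(input, threshold = "otsu") {
  avg <- (input@minip + input@sum) / 2
  cut <- if (identical(threshold, "otsu")) .otsuCut(avg)
         else as.numeric(threshold)
  .asMask((avg >= cut) * 1L)
}

#' Raw-intensity Otsu baseline segmenter
#'
#' Otsu thresholding of the normalized vessel-bright minimum intensity
#' projection -- the no-preprocessing reference against which the fused
#' texture input is compared.
#'
#' @param seq a \code{DSASequence}
#' @return binary mask matrix
#' @export
segmentRawOtsu <- function(seq) {
  proj <- normalizeFrame(.brightProjection(seq))
  .asMask((proj >= .otsuCut(proj)) * 1L)
}
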