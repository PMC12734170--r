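# Reading, writing and polarity handling for angiographic sequences and
# binary vessel masks. On-disk formats: 8-bit grayscale PNG, 8/16-bit
# single- or multi-page grayscale TIFF, and YAML manifests listing frame
# files in temporal order. Masks are 8-bit PNG with 0/255 values.

# bit depth of a PNG file from its IHDR chunk (byte 25 of the file)
.pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])
}

# read one grayscale image file as an integer-mode matrix + gray levels
.readFrame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L)
      stop(sprintf("unsupported mode: '%s' is not single-channel grayscale", path))
    bits <- .pngBitDepth(path)
    G <- 2^bits
    list(frames = list(round(px * (G - 1))), grayLevels = G)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1L]], "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    for (p in pages) if (length(dim(p)) == 3L)
      stop(sprintf("unsupported mode: '%s' is not single-channel grayscale", path))
    list(frames = lapply(pages, function(p) p + 0), grayLevels = 2^bits)
  } else {
    stop(sprintf("unsupported file type: '%s'", path))
  }
}

#' Load an angiographic sequence
#'
#' Accepts an ordered vector of single-frame PNG/TIFF paths, one
#' multi-page TIFF, or a YAML manifest (a list of frame paths in temporal
#' order). Frames are returned in input/page order as an integer-mode
#' \code{\link{DSASequence}} with the gray-level count inferred from the
#' file bit depth (8-bit: G = 256, 16-bit: G = 65536).
#'
#' @param paths character vector of file paths, a single multi-page TIFF,
#'   or a \code{.yaml}/\code{.yml} manifest
#' @param polarity vessel polarity of the stored frames; raw subtraction
#'   angiograms show vessels dark, hence the default
#' @param frameRate acquisition frame rate (metadata)
#' @param view acquisition view (metadata)
#' @return a \code{DSASequence}
#' @export
loadSequence <- function(paths, polarity = "vessel_dark", frameRate = 4,
                         view = "unknown") {
  if (length(paths) == 0L) stop("empty input: no frame paths given")
  if (length(paths) == 1L &&
      tolower(tools::file_ext(paths)) %in% c("yaml", "yml")) {
    paths <- unlist(yaml::read_yaml(paths))
    if (length(paths) == 0L) stop("empty input: manifest lists no frames")
  }
  for (p in paths) if (!file.exists(p)) stop(sprintf("file not found: '%s'", p))
  frames <- list(); G <- NULL
  for (p in paths) {
    fr <- .readFrame(p)
    if (is.null(G)) G <- fr$grayLevels
    else if (G != fr$grayLevels) stop("mixed bit depths across frames")
    frames <- c(frames, fr$frames)
  }
  d <- dim(frames[[1L]])
  for (f in frames) if (!identical(dim(f), d))
    stop("shape mismatch: frames differ in dimensions")
  DSASequence(frames, polarity = polarity, frameRate = frameRate,
              view = view, grayLevels = G, mode = "integer")
}

#' Write a sequence as one multi-page grayscale TIFF
#'
#' Round-trips losslessly through \code{\link{loadSequence}} for 8- and
#' 16-bit integer-mode sequences.
#'
#' @param seq a \code{DSASequence} in integer mode
#' @param path output file path
#' @export
saveSequence <- function(seq, path) {
  if (seq@mode != "integer") stop("only integer-mode sequences are written")
  G <- seq@grayLevels
  bits <- if (G <= 256) 8L else 16L
  pages <- lapply(seq_len(nFrames(seq)),
                  function(i) getFrame(seq, i) / (G - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Convert a sequence to the vessel-bright convention
#'
#' All texture descriptors assume contrast-filled vessels brighter than
#' their surroundings. Raw subtraction angiograms show vessels dark, so
#' dark-polarity frames are inverted (\code{(G-1) - I}, or \code{1 - I} in
#' normalized mode) and the polarity flag flips; bright sequences are
#' returned unchanged. The underlying inversion is an involution.
#'
#' @param seq a \code{DSASequence}
#' @return a vessel-bright \code{DSASequence}
#' @export
toVesselBright <- function(seq) {
  if (seq@polarity == "vessel_bright") return(seq)
  top <- if (seq@mode == "integer") seq@grayLevels - 1 else 1
  new("DSASequence", frames = top - seq@frames, frameRate = seq@frameRate,
      polarity = "vessel_bright", view = seq@view,
      grayLevels = seq@grayLevels, mode = seq@mode)
}

#' Min-max normalize one frame to [0,1]
#'
#' Constant frames map to all zeros (a documented convention that keeps
#' batch pipelines total); already-normalized frames spanning [0,1] are
#' returned unchanged.
#'
#' @param frame numeric matrix
#' @export
normalizeFrame <- function(frame) .minmax01(frame)

#' Save / load a binary vessel mask as 8-bit PNG
#'
#' On disk 0 maps to 0 and 1 to 255; the round trip is bit-exact. Loading
#' rejects files containing values other than 0/255 unless
#' \code{tolerant = TRUE}, in which case values >= 128 become vessel.
#'
#' @param mask binary matrix (0/1 or logical)
#' @param path file path
#' @export
saveMask <- function(mask, path) {
  mask <- .asMask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname saveMask
#' @param tolerant accept non-binary PNGs by thresholding at 128
#' @export
loadMask <- function(path, tolerant = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L)
    stop(sprintf("unsupported mode: '%s' is not single-channel grayscale", path))
  v <- round(px * 255)
  if (!tolerant && !all(v %in% c(0, 255)))
    stop(sprintf("format error: '%s' contains non-binary pixel values", path))
  .asMask((v >= 128) * 1L)
}
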