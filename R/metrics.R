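# Confusion-matrix segmentation metrics and batch reports. All ratio
# metrics lie in [0,1]. Degenerate denominators follow the usual
# segmentation-benchmark convention: a metric whose denominator is empty
# scores 1 when the compared sets are both empty and 0 otherwise.

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,gt binary matrices of identical shape (1 = vessel)
#' @return a \code{\link{ConfusionCounts}} object
#' @export
confusionCounts <- function(pred, gt) {
  pred <- .asMask(pred, "pred"); gt <- .asMask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop("shape mismatch between pred and gt")
  tp <- sum(pred == 1L & gt == 1L)
  tn <- sum(pred == 0L & gt == 0L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
}

.ratio <- function(num, den, bothEmpty) {
  if (den == 0) return(if (bothEmpty) 1 else 0)
  num / den
}

#' Overlap and classification metrics from confusion counts
#'
#' DICE = 2TP/(2TP+FP+FN); IoU (Jaccard) = TP/(TP+FP+FN);
#' Accuracy = (TP+TN)/total; Sensitivity = TP/(TP+FN);
#' Specificity = TN/(TN+FP); Precision = TP/(TP+FP); F1 is the harmonic
#' mean of precision and sensitivity (identical to DICE for binary masks,
#' kept as an independent code path).
#'
#' @param c a \code{\link{ConfusionCounts}} object
#' @return numeric in [0,1]
#' @export
diceScore <- function(c) .ratio(2 * c@tp, 2 * c@tp + c@fp + c@fn, TRUE)

#' @rdname diceScore
#' @export
iouScore <- function(c) .ratio(c@tp, c@tp + c@fp + c@fn, TRUE)

#' @rdname diceScore
#' @export
accuracyScore <- function(c)
  .ratio(c@tp + c@tn, c@tp + c@tn + c@fp + c@fn, TRUE)

#' @rdname diceScore
#' @export
sensitivityScore <- function(c) .ratio(c@tp, c@tp + c@fn, c@fp == 0)

#' @rdname diceScore
#' @export
specificityScore <- function(c) .ratio(c@tn, c@tn + c@fp, c@fn == 0)

#' @rdname diceScore
#' @export
precisionScore <- function(c) .ratio(c@tp, c@tp + c@fp, c@fn == 0)

#' @rdname diceScore
#' @export
f1Score <- function(c) {
  p <- precisionScore(c); s <- sensitivityScore(c)
  if (p + s == 0) return(0)
  2 * p * s / (p + s)
}

#' All seven metrics of one mask pair as a named vector
#'
#' @param pred,gt binary matrices of identical shape
#' @return named numeric vector (dice, iou, accuracy, sensitivity,
#'   specificity, precision, f1)
#' @export
segmentationMetrics <- function(pred, gt) {
  cc <- confusionCounts(pred, gt)
  c(dice = diceScore(cc), iou = iouScore(cc),
    accuracy = accuracyScore(cc), sensitivity = sensitivityScore(cc),
    specificity = specificityScore(cc), precision = precisionScore(cc),
    f1 = f1Score(cc))
}

#' Evaluate a batch of mask pairs
#'
#' Computes per-image metrics and summarises each as mean, sample
#' standard deviation and a normal-approximation 95 percent confidence
#' interval (mean +/- 1.96 sd / sqrt(n)). Vessel Connectivity is included
#' when \code{vc = TRUE} (requires non-empty ground-truth masks).
#'
#' @param preds,gts lists of binary matrices, pairwise matched
#' @param vc also compute the Vessel Connectivity metric per pair
#' @param rMatch matching radius for VC
#' @param names optional image identifiers
#' @return list with \code{perImage} (data.frame, one row per pair) and
#'   \code{summary} (data.frame with mean, sd, ci_lower, ci_upper per
#'   metric)
#' @export
evaluateBatch <- function(preds, gts, vc = FALSE, rMatch = 2,
                          names = NULL) {
  if (length(preds) == 0L) stop("empty input: no mask pairs")
  if (length(preds) != length(gts))
    stop("preds and gts must have equal length")
  if (is.null(names)) names <- sprintf("image_%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    m <- segmentationMetrics(preds[[i]], gts[[i]])
    if (vc) m <- c(m, vc = vesselConnectivity(gts[[i]], preds[[i]],
                                              rMatch = rMatch)@vc)
    m
  })
  per <- as.data.frame(do.call(rbind, rows))
  per <- cbind(image = names, per)
  n <- nrow(per)
  num <- per[, -1L, drop = FALSE]
  mu <- colMeans(num)
  sdev <- apply(num, 2, stats::sd)
  if (n == 1L) sdev[] <- 0
  half <- 1.96 * sdev / sqrt(n)
  summ <- data.frame(metric = colnames(num), mean = mu, sd = sdev,
                     ci_lower = mu - half, ci_upper = mu + half,
                     row.names = NULL)
  list(perImage = per, summary = summ)
}
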