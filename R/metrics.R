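# Evaluation against ground truth: confusion counts, the five headline
# metrics (sensitivity, specificity, accuracy, Jaccard similarity, Matthews
# correlation) and tumor-burden areas (core / enhancement / whole tumor).

#' Pixelwise confusion counts of two binary masks
#'
#' @param pred_mask,truth_mask equal-shape logical (or 0/1) matrices.
#' @return list with `TP`, `TN`, `FP`, `FN` (sum = pixel count).
#' @export
confusion <- function(pred_mask, truth_mask) {
  if (!all(dim(pred_mask) == dim(truth_mask)))
    stop("masks must have identical dimensions", call. = FALSE)
  p <- as.logical(pred_mask); t <- as.logical(truth_mask)
  if (anyNA(p) || anyNA(t)) stop("masks must be binary without NA", call. = FALSE)
  list(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

metric_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Segmentation metric report from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, Jaccard similarity `TP/(TP+FP+FN)` and the Matthews
#' correlation coefficient. Zero-denominator cases return `NA` and are
#' listed in the `undefined` field, never silently 0.
#'
#' @param c confusion counts from [confusion()] (or a list with TP/TN/FP/FN).
#' @return `metric_report` list with the five metrics and `undefined`
#'   (character vector of metrics whose denominator vanished).
#' @export
metric_report <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts", call. = FALSE)
  total <- TP + TN + FP + FN
  if (total == 0) stop("all-zero confusion counts", call. = FALSE)
  sens <- metric_or_na(TP, TP + FN)
  spec <- metric_or_na(TN, TN + FP)
  acc <- (TP + TN) / total
  jsi <- metric_or_na(TP, TP + FP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              jsi = jsi, mcc = mcc)
  out$undefined <- names(out)[vapply(out, function(v) is.na(v), logical(1))]
  class(out) <- "metric_report"
  out
}

#' Tumor-burden areas from a phantom-style label map
#'
#' Pixel counts of the tumor core (class 3) and enhancement rim (class 4);
#' the whole tumor is their union.
#'
#' @param labelmap integer matrix using the phantom class ids 0..4.
#' @return list with `tc_area`, `et_area`, `wt_area` (pixels).
#' @export
tumor_burden <- function(labelmap) {
  ids <- unique(as.integer(labelmap))
  bad <- setdiff(ids, unname(PHANTOM_CLASSES))
  if (length(bad))
    stop("unknown label classes: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  tc <- sum(labelmap == PHANTOM_CLASSES[["tumor_core"]])
  et <- sum(labelmap == PHANTOM_CLASSES[["enhancement_rim"]])
  list(tc_area = tc, et_area = et, wt_area = tc + et)
}
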