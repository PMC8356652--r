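#' @keywords internal
"_PACKAGE"

# Intensities live on a fixed 0-255 scale; images are numeric matrices
# (row, col) with 0-based coordinates reported as (row, col) top-left origin.

clip255 <- function(x) pmin(pmax(x, 0), 255)

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg), call. = FALSE)
  if (anyNA(img)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  invisible(img)
}

#' Histogram of an 8-bit grayscale image
#'
#' Counts over the 256 intensity levels 0..255 (values are rounded and
#' clipped first).
#'
#' @param img numeric matrix of intensities on the 0-255 scale.
#' @return integer vector of length 256 with `names` "0".."255".
#' @export
image_histogram <- function(img) {
  assert_gray(img)
  counts <- tabulate(as.integer(round(clip255(img))) + 1L, nbins = 256L)
  names(counts) <- as.character(0:255)
  counts
}

#' Robust noise standard-deviation estimate
#'
#' Median absolute deviation of the 4-neighbour Laplacian residual,
#' rescaled so the estimate is unbiased for i.i.d. Gaussian noise
#' (the Laplacian response `4c - sum(neighbours)` has variance `20 sigma^2`).
#'
#' @param img numeric intensity matrix.
#' @return estimated noise SD (>= 0).
#' @export
estimate_noise_sd <- function(img) {
  assert_gray(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) return(0)
  c0 <- img[2:(h - 1), 2:(w - 1)]
  lap <- 4 * c0 -
    img[1:(h - 2), 2:(w - 1)] - img[3:h, 2:(w - 1)] -
    img[2:(h - 1), 1:(w - 2)] - img[2:(h - 1), 3:w]
  stats::mad(as.numeric(lap), center = 0) / sqrt(20)
}

# Shift a matrix by (dr, dc) with replicate (nearest-edge) padding.
shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Dice similarity of two binary masks
#'
#' @param a,b logical (or 0/1) matrices of equal shape.
#' @return `2|a&b| / (|a|+|b|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical dimensions", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Greedy best-match Dice between two label maps: for each truth label,
# the best Dice over predicted labels. Returns a named numeric vector.
best_match_dice <- function(pred_labels, truth_labels) {
  stopifnot(all(dim(pred_labels) == dim(truth_labels)))
  tl <- sort(unique(as.integer(truth_labels)))
  pl <- sort(unique(as.integer(pred_labels)))
  out <- vapply(tl, function(t) {
    tm <- truth_labels == t
    max(vapply(pl, function(p) dice(pred_labels == p, tm), numeric(1)))
  }, numeric(1))
  names(out) <- as.character(tl)
  out
}
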