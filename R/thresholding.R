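# Fuzzy entropy-based thresholding (FET) and the variance statistics feeding
# the HARIS fitness: between-class (interclass) variance at a cut, and the
# intraclass correlation homogeneity ratio of a segment.

check_histogram <- function(counts) {
  if (length(counts) != 256 || any(counts < 0) || anyNA(counts))
    stop("histogram must be 256 nonnegative counts", call. = FALSE)
  if (sum(counts) <= 0) stop("histogram is empty", call. = FALSE)
  invisible(counts)
}

#' Fuzzy entropy-based threshold of a 256-level histogram
#'
#' Scans all 254 interior cut candidates t (class 1 = intensities <= t,
#' class 2 = intensities > t) and scores each with a fuzzy-entropy statistic;
#' ties break toward the smaller t. Three forms of the statistic are
#' available:
#'
#' * `"entropy"` (default): each intensity's membership to its own side is
#'   `1 / (1 + |i - mu_side| / C)` with `mu_side` the side's mean intensity
#'   and `C = 255`; the score is the histogram-weighted binary Shannon
#'   entropy (base 2) of those memberships, and the *minimizing* t is
#'   returned. Crisp memberships (pixels near their class mean) give low
#'   entropy, so the optimum separates the intensity modes.
#' * `"printed"`: the difference form
#'   `sum_{i<=t} p(i) mu_tc(i) log2 mu_tc(i) - sum_{i>t} p(i) mu_ntc(i) log2 mu_ntc(i)`
#'   with complementary logistic memberships centred at t (slope 1/8 per
#'   intensity unit), maximized. Kept for fidelity; see the methods vignette
#'   for why it is not the default.
#' * `"sum"`: the conventional total fuzzy entropy
#'   `-sum p(i) [mu log2 mu]` over both sides with the same logistic
#'   memberships, minimized.
#'
#' @param hist integer vector of 256 counts (see [image_histogram()]).
#' @param fet_form one of `"entropy"`, `"printed"`, `"sum"`.
#' @param slope logistic slope (intensity units) for the logistic forms.
#' @return a `threshold_model` list: `threshold` (the chosen t, in (0,255)),
#'   `scores` (length-254 numeric, one per candidate), `form`, and the two
#'   membership functions `membership_tc(i)` / `membership_ntc(i)` frozen at
#'   the chosen t.
#' @export
fet_threshold <- function(hist, fet_form = c("entropy", "printed", "sum"),
                          slope = 8) {
  check_histogram(hist)
  fet_form <- match.arg(fet_form)
  if (sum(hist > 0) < 2)
    stop("degenerate histogram: fewer than two occupied intensity levels",
         call. = FALSE)
  p <- hist / sum(hist)
  i <- 0:255
  ts <- 1:254
  scores <- vapply(ts, function(t) fet_score(p, i, t, fet_form, slope),
                   numeric(1))
  best <- if (fet_form == "printed") {
    ts[which.max(scores)]          # maximize, ties -> smaller t
  } else {
    ts[which.min(scores)]          # minimize, ties -> smaller t
  }
  t <- best
  if (fet_form == "entropy") {
    lo <- i <= t
    m0 <- sum(i[lo] * p[lo]) / max(sum(p[lo]), .Machine$double.eps)
    m1 <- sum(i[!lo] * p[!lo]) / max(sum(p[!lo]), .Machine$double.eps)
    mem_tc  <- function(x) 1 / (1 + abs(x - m1) / 255)  # tumor side = above t
    mem_ntc <- function(x) 1 / (1 + abs(x - m0) / 255)
  } else {
    mem_ntc <- function(x) 1 / (1 + exp(-(x - t) / slope))
    mem_tc  <- function(x) 1 - mem_ntc(x)
  }
  structure(list(threshold = t, scores = scores, form = fet_form,
                 membership_tc = mem_tc, membership_ntc = mem_ntc),
            class = "threshold_model")
}

fet_score <- function(p, i, t, form, slope) {
  lo <- i <= t
  if (form == "entropy") {
    p_lo <- sum(p[lo]); p_hi <- sum(p[!lo])
    if (p_lo == 0 || p_hi == 0) return(Inf)
    m0 <- sum(i[lo] * p[lo]) / p_lo
    m1 <- sum(i[!lo] * p[!lo]) / p_hi
    mu <- ifelse(lo, 1 / (1 + abs(i - m0) / 255), 1 / (1 + abs(i - m1) / 255))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    return(sum(p * (-mu * log2(mu) - (1 - mu) * log2(1 - mu))))
  }
  mu_ntc <- 1 / (1 + exp(-(i - t) / slope))
  mu_tc <- 1 - mu_ntc
  xlx <- function(u) ifelse(u > 0, u * log2(u), 0)
  a <- sum(p[lo] * xlx(mu_tc[lo]))
  b <- sum(p[!lo] * xlx(mu_ntc[!lo]))
  if (form == "printed") a - b else -(a + b)
}

#' Between-class (interclass) variance of a histogram at a cut
#'
#' The Otsu-form statistic `w1 * w2 * (mu1 - mu2)^2` for the split
#' below/at-or-above `Ct`. An empty side yields 0 by convention.
#'
#' @param hist 256 counts.
#' @param Ct cut intensity, 0 < Ct < 255; class 1 is `x < Ct`.
#' @return nonnegative variance (intensity^2 units).
#' @export
interclass_variance <- function(hist, Ct) {
  check_histogram(hist)
  if (Ct <= 0 || Ct >= 255) stop("Ct must lie strictly inside (0, 255)", call. = FALSE)
  p <- hist / sum(hist)
  i <- 0:255
  lo <- i < Ct
  w1 <- sum(p[lo]); w2 <- sum(p[!lo])
  if (w1 == 0 || w2 == 0) return(0)
  mu1 <- sum(i[lo] * p[lo]) / w1
  mu2 <- sum(i[!lo] * p[!lo]) / w2
  w1 * w2 * (mu1 - mu2)^2
}

#' Cut maximizing the between-class variance
#'
#' Exhaustive scan of all interior cuts (ties toward the smaller cut).
#'
#' @param hist 256 counts.
#' @return the argmax cut in 1..254.
#' @export
otsu_cut <- function(hist) {
  check_histogram(hist)
  v <- vapply(1:254, function(ct) interclass_variance(hist, ct), numeric(1))
  (1:254)[which.max(v)]
}

#' Intraclass correlation of a segment
#'
#' Homogeneity ratio `sigma_s^2 / (sigma_s^2 + sigma_i^2)` in \[0, 1\]:
#' 0 for a perfectly homogeneous segment, 0.5 when the segment is as
#' variable as the whole image.
#'
#' @param segment_sd intensity SD within the segment (>= 0).
#' @param image_sd intensity SD of the whole image (>= 0).
#' @return ratio in \[0, 1\].
#' @export
intraclass_correlation <- function(segment_sd, image_sd) {
  if (segment_sd < 0 || image_sd < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  if (segment_sd == 0 && image_sd == 0)
    stop("segment and image SD cannot both be zero", call. = FALSE)
  segment_sd^2 / (segment_sd^2 + image_sd^2)
}
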