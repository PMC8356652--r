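# Adaptive bilateral filter: per pixel, a fuzzy-weighted centroid of the
# neighbourhood whose center target is the contra-harmonic mean (the local
# brightness reference), with spatial memberships (Gaussian in pixel
# distance) and a Bayesian "pixel likeliness" factor on the intensity
# difference acting as the edge-stopping range kernel. Constant images are
# exact fixed points; output stays on the 0-255 scale.

#' Adaptive bilateral filter configuration
#'
#' @param window_radius neighbourhood half-width in pixels (>= 1).
#' @param fuzzifier_x fuzzifier exponent applied to the membership weights
#'   in the weighted centroid (> 1).
#' @param n_classes_for_likeliness number of intensity classes behind the
#'   likeliness prior (the threshold split gives 2; kept as a field for
#'   forward compatibility).
#' @param epsilon small positive stabilizer guarding divisions.
#' @param passes number of filter applications (>= 1); each pass re-derives
#'   the likeliness model from its own input.
#' @return a `filter_config` list.
#' @export
filter_config <- function(window_radius = 3, fuzzifier_x = 2,
                          n_classes_for_likeliness = 2, epsilon = 1e-8,
                          passes = 2) {
  if (window_radius < 1) stop("window_radius must be >= 1", call. = FALSE)
  if (fuzzifier_x <= 1) stop("fuzzifier_x must be > 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (passes < 1) stop("passes must be >= 1", call. = FALSE)
  structure(list(window_radius = as.integer(window_radius),
                 fuzzifier_x = fuzzifier_x,
                 n_classes_for_likeliness = as.integer(n_classes_for_likeliness),
                 epsilon = epsilon, passes = as.integer(passes)),
            class = "filter_config")
}

#' Contra-harmonic mean of a neighbourhood
#'
#' `sum(i^2) / sum(i)`; always >= the arithmetic mean for positive data.
#' An all-zero window returns 0 by convention (not a division failure).
#'
#' @param values numeric vector of intensities (nonnegative).
#' @return the contra-harmonic mean.
#' @export
contra_harmonic_alpha <- function(values) {
  if (length(values) == 0) stop("empty window", call. = FALSE)
  if (any(values < 0)) stop("intensities must be nonnegative", call. = FALSE)
  s <- sum(values)
  if (s == 0) return(0)
  sum(values^2) / s
}

#' Fuzzy-weighted pixel belongingness
#'
#' The weighted centroid `sum(c^x * p) / sum(c^x)` of window intensities
#' `p` under membership weights `c` raised to the fuzzifier exponent `x`.
#'
#' @param window numeric vector of intensities.
#' @param memberships weights in \[0, 1\], same length, not all zero.
#' @param fuzzifier_x fuzzifier exponent (> 0).
#' @return the centroid intensity.
#' @export
pixel_belongingness <- function(window, memberships, fuzzifier_x = 2) {
  if (length(window) != length(memberships))
    stop("window and memberships must have the same length", call. = FALSE)
  if (any(memberships < 0 | memberships > 1))
    stop("memberships must lie in [0, 1]", call. = FALSE)
  w <- memberships^fuzzifier_x
  if (sum(w) == 0)
    stop("all-zero memberships in pixel_belongingness", call. = FALSE)
  sum(w * window) / sum(w)
}

#' Bayesian pixel likeliness
#'
#' Posterior probability of a class given an observation:
#' `prior_s * density_s(v) / sum_k prior_k * density_k(v)`. Zero total
#' evidence returns the uniform posterior `1/K` with a warning.
#'
#' @param value the observed intensity (or intensity difference).
#' @param class_models list of classes, each a list with `prior` and
#'   `density` (a function of the value); priors must sum to 1.
#' @param class index of the class whose posterior is returned (default 1).
#' @return posterior probability in \[0, 1\].
#' @export
pixel_likeliness <- function(value, class_models, class = 1L) {
  priors <- vapply(class_models, function(m) m$prior, numeric(1))
  if (abs(sum(priors) - 1) > 1e-8)
    stop("class priors must sum to 1", call. = FALSE)
  ev <- vapply(class_models, function(m) m$prior * m$density(value), numeric(1))
  tot <- sum(ev)
  if (tot <= 0) {
    warning("zero total evidence; returning uniform posterior")
    return(1 / length(class_models))
  }
  ev[[class]] / tot
}

# Same-class posterior as a function of intensity difference magnitude:
# same-class differences ~ N(0, sqrt(2) * sigma_n), different-class
# differences ~ uniform over 0..255; the same-class prior is the chance two
# random pixels fall on the same side of the FET threshold split.
likeliness_models <- function(img, epsilon = 1e-8) {
  sigma_n <- max(estimate_noise_sd(img), 0.5)
  hist <- image_histogram(img)
  q <- if (sum(hist > 0) >= 2) {
    t <- fet_threshold(hist)$threshold
    sum(hist[seq_len(t + 1)]) / sum(hist)
  } else 1
  prior_same <- min(max(q^2 + (1 - q)^2, epsilon), 1 - epsilon)
  list(
    same = list(prior = prior_same,
                density = function(d) stats::dnorm(d, 0, sqrt(2) * sigma_n)),
    different = list(prior = 1 - prior_same,
                     density = function(d) rep(1 / 256, length(d)))
  )
}

#' Adaptive bilateral filter
#'
#' Each output pixel is the fuzzy-weighted centroid ([pixel_belongingness()])
#' of its neighbourhood: each neighbour's membership is a spatial Gaussian
#' `exp(-d^2 / (2 r^2))` times the Bayesian likeliness
#' ([pixel_likeliness()]) that the intensity difference is same-class rather
#' than cross-edge, and the center's own intensity is replaced by a
#' contra-harmonic brightness target ([contra_harmonic_alpha()]): the
#' same-class-weighted contra-harmonic mean of the neighbours, falling back
#' smoothly to the plain window contra-harmonic mean when no same-class
#' evidence exists (which is what suppresses isolated impulses). Constant
#' images are exact fixed points; output is clipped to \[0, 255\] and keeps
#' the input dimensions.
#'
#' @param img numeric intensity matrix (0-255 scale).
#' @param cfg a [filter_config()]; `passes > 1` iterates the filter.
#' @return filtered matrix, same shape.
#' @export
adaptive_bilateral_filter <- function(img, cfg = filter_config()) {
  assert_gray(img)
  r <- cfg$window_radius
  if (2 * r + 1 > min(dim(img)))
    stop(sprintf("window_radius %d exceeds the image half-extent", r),
         call. = FALSE)
  out <- img
  for (p in seq_len(cfg$passes)) out <- abf_pass(out, cfg)
  out
}

abf_pass <- function(img, cfg) {
  r <- cfg$window_radius
  models <- likeliness_models(img, cfg$epsilon)
  p_same <- function(d) {
    ev_s <- models$same$prior * models$same$density(d)
    ev_d <- models$different$prior * models$different$density(d)
    ev_s / (ev_s + ev_d)
  }

  offs <- expand.grid(dr = -r:r, dc = -r:r)
  zero <- matrix(0, nrow(img), ncol(img))
  num_n <- zero; den_n <- zero             # neighbour centroid terms
  wi <- zero; wi2 <- zero                  # same-class contra-harmonic sums
  s1 <- zero; s2 <- zero                   # plain window sums (incl. center)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    sh <- shift_pad(img, dr, dc)
    s1 <- s1 + sh; s2 <- s2 + sh * sh
    if (dr == 0 && dc == 0) next
    spatial <- exp(-(dr^2 + dc^2) / (2 * r^2))
    w <- spatial * p_same(abs(sh - img))
    wx <- w^cfg$fuzzifier_x
    num_n <- num_n + wx * sh
    den_n <- den_n + wx
    wi <- wi + wx * sh
    wi2 <- wi2 + wx * sh * sh
  }
  alpha_plain <- ifelse(s1 > 0, s2 / s1, 0)
  alpha_same <- ifelse(wi > cfg$epsilon, wi2 / wi, alpha_plain)
  w0 <- 0.5                                # plain-target fallback mass
  alpha <- (den_n * alpha_same + w0 * alpha_plain) / (den_n + w0)
  wx_c <- p_same(0)^cfg$fuzzifier_x        # center weight (spatial = 1)
  clip255((wx_c * alpha + num_n) / pmax(wx_c + den_n, cfg$epsilon))
}
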