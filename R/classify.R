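# Tumor / non-tumor classification. The Adaptive Structural Similarity
# Index (ASSI) scores a window against a tumor reference as the classical
# SSIM luminance/contrast/structure product reweighted by a noise-adaptive
# factor omega = sigma_p^2 / (sigma_p^2 + sigma_e^2 / 2). The correlation
# index (CI) of each pixel or region against the reference drives the
# "CI > Threshold => tumorous" rule; an alternative fuzzy-membership
# assignment reassigns pixels to region vertices with homogeneity-scaled
# distances and overshooting vertex updates.

#' ASSI configuration
#'
#' Stabilizers default to the standard SSIM constants
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`, `C3 = C2 / 2`.
#'
#' @param window odd window size in pixels (>= 3).
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure factors (>= 0; 1 recovers the SSIM product).
#' @param C1,C2,C3 positive stabilizers.
#' @param sigma_e noise SD estimate behind omega; `NULL` means estimate it
#'   from the image via [estimate_noise_sd()].
#' @param ci_threshold correlation-index cut for the tumorous decision;
#'   `NULL` (default) selects the adaptive region-mode rule described in
#'   [classify_pixels()].
#' @return an `assi_config` list.
#' @export
assi_config <- function(window = 3, alpha = 1, beta = 1, gamma = 1,
                        C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2, C3 = C2 / 2,
                        sigma_e = NULL, ci_threshold = NULL) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3", call. = FALSE)
  if (C1 <= 0 || C2 <= 0 || C3 <= 0) stop("stabilizers must be > 0", call. = FALSE)
  if (!is.null(sigma_e) && sigma_e < 0) stop("sigma_e must be >= 0", call. = FALSE)
  if (alpha < 0 || beta < 0 || gamma < 0) stop("exponents must be >= 0", call. = FALSE)
  structure(list(window = as.integer(window), alpha = alpha, beta = beta,
                 gamma = gamma, C1 = C1, C2 = C2, C3 = C3,
                 sigma_e = sigma_e, ci_threshold = ci_threshold),
            class = "assi_config")
}

# population moments of a window (denominator n, matching the sliding
# implementation)
win_moments <- function(w) {
  n <- length(w)
  mu <- mean(w)
  list(mu = mu, var = sum((w - mu)^2) / n)
}

#' Adaptive structural similarity of two windows
#'
#' `omega * x^alpha * y^beta * z^gamma` with luminance
#' `x = (2 mu_p mu_q + C1) / (mu_p^2 + mu_q^2 + C1)`, contrast
#' `y = (2 sigma_p sigma_q + C2) / (sigma_p^2 + sigma_q^2 + C2)`, structure
#' `z = (sigma_pq + C3) / (sigma_p sigma_q + C3)` and
#' `omega = sigma_p^2 / (sigma_p^2 + sigma_e^2 / 2)` (defined as 1 when both
#' variances vanish, i.e. no noise and a flat patch). The first argument is
#' the reference/template window: omega weighs the score by the confidence
#' that the reference's structure rises above the noise floor, so it is a
#' shared factor when many candidates are compared against one reference.
#'
#' @param patch_p,patch_q equal-shape numeric matrices (or vectors);
#'   `patch_p` is the reference.
#' @param cfg an [assi_config()]; `sigma_e = NULL` is not allowed here
#'   (supply one, or use [classify_pixels()] which estimates it).
#' @return the ASSI score (finite).
#' @export
assi <- function(patch_p, patch_q, cfg = assi_config(sigma_e = 0)) {
  if (!all(dim(as.matrix(patch_p)) == dim(as.matrix(patch_q))))
    stop("windows must have identical shapes", call. = FALSE)
  sigma_e <- cfg$sigma_e
  if (is.null(sigma_e))
    stop("assi() needs an explicit sigma_e in the config", call. = FALSE)
  p <- as.numeric(patch_p); q <- as.numeric(patch_q)
  mp <- win_moments(p); mq <- win_moments(q)
  n <- length(p)
  cov_pq <- sum((p - mp$mu) * (q - mq$mu)) / n
  sp <- sqrt(mp$var); sq <- sqrt(mq$var)
  x <- (2 * mp$mu * mq$mu + cfg$C1) / (mp$mu^2 + mq$mu^2 + cfg$C1)
  y <- (2 * sp * sq + cfg$C2) / (mp$var + mq$var + cfg$C2)
  z <- (cov_pq + cfg$C3) / (sp * sq + cfg$C3)
  denom <- mp$var + sigma_e^2 / 2
  omega <- if (denom == 0) 1 else mp$var / denom
  omega * x^cfg$alpha * y^cfg$beta * z^cfg$gamma
}

# Sliding-window CI map of an image against a fixed reference patch.
# Reflect-free replicate padding via shift_pad; all terms vectorized over
# window offsets.
ci_map <- function(img, reference, cfg) {
  win <- cfg$window
  if (!is.matrix(reference) || !all(dim(reference) == c(win, win)))
    stop("reference must be a window-sized matrix", call. = FALSE)
  sigma_e <- if (is.null(cfg$sigma_e)) estimate_noise_sd(img) else cfg$sigma_e
  r <- (win - 1L) / 2L
  n <- win * win
  mq <- mean(reference); vq <- sum((reference - mq)^2) / n
  s1 <- matrix(0, nrow(img), ncol(img)); s2 <- s1; sxq <- s1
  for (dr in -r:r) for (dc in -r:r) {
    sh <- shift_pad(img, dr, dc)
    s1 <- s1 + sh
    s2 <- s2 + sh * sh
    sxq <- sxq + sh * reference[dr + r + 1L, dc + r + 1L]
  }
  mu <- s1 / n
  vp <- pmax(s2 / n - mu^2, 0)
  cov_pq <- sxq / n - mu * mq
  sp <- sqrt(vp); sq <- sqrt(vq)
  x <- (2 * mu * mq + cfg$C1) / (mu^2 + mq^2 + cfg$C1)
  y <- (2 * sp * sq + cfg$C2) / (vp + vq + cfg$C2)
  z <- (cov_pq + cfg$C3) / (sp * sq + cfg$C3)
  denom <- vq + sigma_e^2 / 2
  omega <- if (denom == 0) 1 else vq / denom
  omega * x^cfg$alpha * y^cfg$beta * z^cfg$gamma
}

#' Classify pixels as tumorous by correlation index against a reference
#'
#' Computes the sliding-window ASSI correlation index (CI) of every pixel
#' against the tumor reference patch and applies the
#' `CI > ci_threshold => tumorous` rule. In `mode = "region"` (the pipeline
#' default) the decision is taken per region of a supplied label map: a
#' region whose mean CI (over `roi` pixels) exceeds the threshold is
#' tumorous as a whole, which is robust on flat noisy interiors where
#' per-pixel structure terms decorrelate.
#'
#' @param img numeric intensity matrix.
#' @param reference window-sized matrix (tumor exemplar), e.g. from
#'   [bootstrap_reference()] or the experience store.
#' @param cfg an [assi_config()]; a `NULL` `ci_threshold` means the
#'   adaptive rule (region mode only): the midpoint between the dominant
#'   (most populous) region's CI and the maximum region CI, so the decision
#'   is robust to the multiplicative wobble of the structure and noise
#'   factors.
#' @param mode `"pixel"` (sliding-window CI per pixel) or `"region"`
#'   (one representative interior window per region, cut at its local-best
#'   feature pixel; the whole region is classified at once).
#' @param labels integer label map (required for `mode = "region"`).
#' @param roi optional logical matrix restricting the decision (e.g. a
#'   brain mask); pixels outside are never tumorous.
#' @return logical mask, same shape as `img`; in pixel mode the CI map is
#'   attached as attribute `"ci"`, in region mode the per-region CI table
#'   as attribute `"region_ci"`.
#' @export
classify_pixels <- function(img, reference, cfg = assi_config(),
                            mode = c("pixel", "region"),
                            labels = NULL, roi = NULL) {
  assert_gray(img)
  mode <- match.arg(mode)
  if (is.null(reference))
    stop(paste("no tumor reference available and the experience store is",
               "empty; run with `--bootstrap-reference` (bootstrap_reference())"),
         call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  acfg <- cfg
  if (is.null(acfg$sigma_e)) acfg$sigma_e <- estimate_noise_sd(img)
  if (mode == "pixel") {
    if (is.null(acfg$ci_threshold))
      stop("pixel mode needs an explicit ci_threshold", call. = FALSE)
    ci <- ci_map(img, reference, acfg)
    mask <- ci > acfg$ci_threshold & roi
    attr(mask, "ci") <- ci
    return(mask)
  }
  if (is.null(labels)) stop("mode = 'region' needs a label map", call. = FALSE)
  labs <- sort(unique(as.integer(labels)))
  tab <- do.call(rbind, lapply(labs, function(j) {
    m <- labels == j & roi
    n <- sum(m)
    if (n == 0) return(NULL)
    rc <- region_rep_pixel(img, m, acfg$window)
    patch <- extract_patch(img, rc[1], rc[2], acfg$window)
    data.frame(label = j, roi_pixels = n,
               ci = assi(reference, patch, acfg))
  }))
  thr <- acfg$ci_threshold
  if (is.null(thr)) {
    dom_ci <- tab$ci[which.max(tab$roi_pixels)]
    thr <- (dom_ci + max(tab$ci)) / 2
  }
  mask <- matrix(FALSE, nrow(img), ncol(img))
  for (j in tab$label[tab$ci > thr]) mask[labels == j & roi] <- TRUE
  attr(mask, "region_ci") <- tab
  attr(mask, "threshold_used") <- thr
  mask
}

#' Bootstrap tumor reference patch
#'
#' Cold-start rule when no experience exists: among regions with pixels in
#' the brain mask, pick the one whose mean intensity deviates most from the
#' dominant (largest) region's mean — the presumptive tumor class — and cut
#' the window centred on its local-best feature pixel.
#'
#' @param img numeric intensity matrix.
#' @param seg a [haris_segment()] result.
#' @param window odd patch size.
#' @param roi optional logical brain mask.
#' @return list with `patch` (window matrix) and `label` (chosen region).
#' @export
bootstrap_reference <- function(img, seg, window = 7, roi = NULL) {
  stats_df <- seg$stats
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  in_roi <- vapply(stats_df$label, function(j) sum(seg$labels == j & roi),
                   numeric(1))
  cand <- stats_df[in_roi > 0, ]
  if (nrow(cand) == 0) stop("no regions inside the ROI", call. = FALSE)
  dominant <- cand$mean[which.max(in_roi[in_roi > 0])]
  pick <- cand[which.max(abs(cand$mean - dominant)), ]
  # center the patch on an interior representative pixel of the chosen
  # region, restricted to ROI members
  m <- seg$labels == pick$label & roi
  rc <- region_rep_pixel(img, m, window)
  patch <- extract_patch(img, rc[1], rc[2], window)
  list(patch = patch, label = pick$label)
}

# Representative pixel of a region: the member nearest the region's median
# intensity, preferring pixels whose whole window lies inside the region
# (8-neighbourhood erosion by the window radius) so representative patches
# never straddle a region boundary.
region_rep_pixel <- function(img, mask, window) {
  r <- (window - 1L) / 2L
  er <- mask
  for (i in seq_len(r)) {
    grown <- er
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) grown <- grown & shift_pad(er, dr, dc)
    if (!any(grown)) break
    er <- grown
  }
  pick <- if (any(er)) er else mask
  idx <- which(pick)
  med <- stats::median(img[which(mask)])
  best <- idx[which.min(abs(img[idx] - med))]
  arrayInd(best, dim(img))
}

# window-sized patch centred at (row, col), replicate-padded at borders
extract_patch <- function(img, row, col, window) {
  r <- (window - 1L) / 2L
  ri <- pmin(pmax(row + (-r:r), 1L), nrow(img))
  ci <- pmin(pmax(col + (-r:r), 1L), ncol(img))
  img[ri, ci, drop = FALSE]
}

check_mem <- function(mem) {
  if (any(mem >= 1)) stop("membership must be < 1", call. = FALSE)
  if (any(mem < 0)) stop("membership must be >= 0", call. = FALSE)
  invisible(mem)
}

#' Fuzzy-membership instance adjustment
#'
#' `vertex - (vertex - instance) / (1 - mem)`: the instance pixel pulled
#' through the region vertex with homogeneity-amplified distance. With
#' `mem = 0` the instance is returned unchanged.
#'
#' @param vertex_pix region vertex intensity.
#' @param instance_pix instance pixel intensity.
#' @param mem_pix membership in \[0, 1).
#' @return adjusted value.
#' @export
fuzzy_membership_assign <- function(vertex_pix, instance_pix, mem_pix) {
  check_mem(mem_pix)
  vertex_pix - (vertex_pix - instance_pix) / (1 - mem_pix)
}

#' Fuzzy vertex update
#'
#' `vertex + (instance - vertex) / (1 - mem)`: the vertex moved toward the
#' instance with homogeneity-amplified step. With `mem = 0` the instance is
#' returned.
#'
#' @param vertex_pix region vertex intensity.
#' @param instance_pix instance pixel intensity (J').
#' @param mem_pix membership in \[0, 1).
#' @return updated vertex.
#' @export
fuzzy_vertex_update <- function(vertex_pix, instance_pix, mem_pix) {
  check_mem(mem_pix)
  vertex_pix + (instance_pix - vertex_pix) / (1 - mem_pix)
}

#' Fuzzy-membership region refinement (the fuzzy classifier variant)
#'
#' Iteratively reassigns pixels to the region vertex minimizing the
#' adjusted distance `|i - vertex| / (1 - mem_r)` (the instance-adjustment
#' rule read as a distance) where `mem_r` is the region's intraclass
#' correlation, then moves each vertex by the vertex-update rule with the
#' region's new mean as the instance. Returns the refined label map and
#' vertices.
#'
#' @param img numeric intensity matrix.
#' @param seg a [haris_segment()] result (starting labels and vertices).
#' @param iterations refinement passes (>= 1).
#' @return list with `labels`, `vertices`, `membership` (per region).
#' @export
fuzzy_segment_refine <- function(img, seg, iterations = 3L) {
  assert_gray(img)
  vertices <- seg$stats$mean
  k <- length(vertices)
  img_sd <- stats::sd(as.numeric(img))
  labels <- seg$labels
  mem <- numeric(k)
  for (it in seq_len(iterations)) {
    for (j in seq_len(k)) {
      v <- img[labels == j]
      sd_j <- if (length(v) < 2) 0 else stats::sd(v)
      mem[j] <- min(intraclass_correlation(sd_j, img_sd), 0.99)
    }
    d <- vapply(seq_len(k),
                function(j) abs(as.numeric(img) - vertices[j]) / (1 - mem[j]),
                numeric(length(img)))
    asg <- max.col(-d, ties.method = "first")
    labels <- matrix(asg, nrow(img), ncol(img))
    for (j in seq_len(k)) {
      v <- img[labels == j]
      if (length(v) == 0) next
      vertices[j] <- clip255(fuzzy_vertex_update(vertices[j], mean(v), mem[j]))
    }
  }
  list(labels = labels, vertices = vertices, membership = mem)
}
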