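# Two-phase HARIS segmentation. Phase 1 sweeps candidate region counts and
# scores each refined intensity partition with a weighted fitness built from
# between-class variance (separation) and intraclass correlation
# (homogeneity); phase 2 assembles pixels into intensity regions around
# per-region local-best feature pixels by Lloyd-style reassignment on the
# 256-bin histogram.

#' HARIS configuration
#'
#' @param weight_x,weight_y deciding-factor weights of the fitness (>= 0,
#'   not both 0): `weight_x` weighs the between-class-variance (separation)
#'   term, `weight_y` the intraclass-correlation (homogeneity) term.
#' @param k_min,k_max candidate region-count bounds. The field-prior default
#'   for full-scale MR slices is `k_min = 23`; desk-scale phantoms with few
#'   classes use small bounds (see the methods vignette).
#' @param max_iterations reassignment iteration cap for phase 2.
#' @param plateau_tol plateau tolerance of the phase-1 selection: the
#'   smallest k scoring within this fraction of the sweep maximum is chosen
#'   (a generalized tie-break toward smaller k).
#' @param seed integer seed (tie-breaking only; the sweep is deterministic).
#' @return a `haris_config` list.
#' @export
haris_config <- function(weight_x = 0.5, weight_y = 0.5,
                         k_min = 23L, k_max = 30L,
                         max_iterations = 50L, plateau_tol = 0.02,
                         seed = 1L) {
  if (weight_x < 0 || weight_y < 0 || (weight_x == 0 && weight_y == 0))
    stop("weights must be >= 0 and not both 0", call. = FALSE)
  if (k_min > k_max) stop("k_min must be <= k_max", call. = FALSE)
  if (k_min < 1) stop("k_min must be >= 1", call. = FALSE)
  structure(list(weight_x = weight_x, weight_y = weight_y,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 max_iterations = as.integer(max_iterations),
                 plateau_tol = plateau_tol, seed = as.integer(seed)),
            class = "haris_config")
}

#' HARIS segment-count fitness (plug-in form)
#'
#' The raw weighted fitness
#' `weight_x * (total_pixels / pixels_in_segment) + weight_y * (segment_sd_term / region_count)`.
#'
#' @param inputs list with `total_pixels`, `pixels_in_segment`,
#'   `segment_sd_term`, `region_count` (all positive).
#' @param cfg a [haris_config()] (only the weights are used).
#' @return finite positive score.
#' @export
haris_objective <- function(inputs, cfg = haris_config()) {
  with(inputs, {
    if (pixels_in_segment <= 0 || region_count <= 0)
      stop("pixels_in_segment and region_count must be positive", call. = FALSE)
    if (total_pixels <= 0 || segment_sd_term < 0)
      stop("invalid objective inputs", call. = FALSE)
    cfg$weight_x * (total_pixels / pixels_in_segment) +
      cfg$weight_y * (segment_sd_term / region_count)
  })
}

# Exact 1-D weighted k-means over the occupied histogram levels by dynamic
# programming (contiguous clusters are optimal in 1-D). Returns the optimal
# boundaries for k clusters.
dp_partition <- function(levels, wts, k) {
  m <- length(levels)
  cw <- cumsum(wts)
  cs <- cumsum(wts * levels)
  cs2 <- cumsum(wts * levels^2)
  seg_cost <- function(i, j) {           # weighted SSE of levels[i..j]
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / w
  }
  D <- matrix(Inf, k, m)
  B <- matrix(1L, k, m)                  # start index of the last cluster
  for (j in seq_len(m)) D[1, j] <- seg_cost(1, j)
  if (k > 1) for (q in 2:k) {
    for (j in q:m) {
      best <- Inf; bi <- q
      for (i in q:j) {
        v <- D[q - 1, i - 1] + seg_cost(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      D[q, j] <- best; B[q, j] <- bi
    }
  }
  # backtrack boundaries
  starts <- integer(k); j <- m
  for (q in k:1) { starts[q] <- B[q, j]; j <- starts[q] - 1L }
  starts
}

# k intensity classes on the 256-bin histogram: exact DP partition as the
# initializer, then Lloyd reassignment to convergence (the DP optimum is a
# Lloyd fixed point, so the trace is short and non-increasing by
# construction). Returns sorted centroids and a per-level assignment.
histogram_kmeans <- function(hist, k, max_iterations = 50L) {
  levels <- which(hist > 0) - 1L           # occupied intensities
  wts <- hist[hist > 0]
  n_distinct <- length(levels)
  merged <- FALSE
  if (k > n_distinct) {
    warning(sprintf("k = %d exceeds %d distinct intensities; duplicate centroids merged",
                    k, n_distinct))
    k <- n_distinct
    merged <- TRUE
  }
  starts <- dp_partition(levels, wts, k)
  bounds <- c(starts, n_distinct + 1L)
  cent <- vapply(seq_len(k), function(q) {
    idx <- bounds[q]:(bounds[q + 1] - 1L)
    sum(levels[idx] * wts[idx]) / sum(wts[idx])
  }, numeric(1))
  wcss_trace <- numeric(0)
  assign_lv <- rep(0L, n_distinct)
  for (it in seq_len(max_iterations)) {
    d <- abs(outer(levels, cent, `-`))
    new_assign <- max.col(-d, ties.method = "first")
    # reseed any empty class at the occupied level farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(d[cbind(seq_len(n_distinct), new_assign)])
        cent[j] <- levels[far]
        d <- abs(outer(levels, cent, `-`))
        new_assign <- max.col(-d, ties.method = "first")
      }
    }
    cent_new <- vapply(seq_len(k), function(j) {
      m <- new_assign == j
      sum(levels[m] * wts[m]) / sum(wts[m])
    }, numeric(1))
    wcss_trace <- c(wcss_trace, sum(wts * (levels - cent_new[new_assign])^2))
    done <- identical(new_assign, assign_lv)
    assign_lv <- new_assign
    cent <- cent_new
    if (done) break
  }
  ord <- order(cent)
  remap <- integer(k); remap[ord] <- seq_len(k)
  full_assign <- integer(256)
  full_assign[levels + 1L] <- remap[assign_lv]
  # unoccupied levels: nearest centroid (for completeness)
  if (any(full_assign == 0L)) {
    miss <- which(full_assign == 0L)
    d <- abs(outer(miss - 1L, cent[ord], `-`))
    full_assign[miss] <- max.col(-d, ties.method = "first")
  }
  list(centroids = cent[ord], level_assign = full_assign,
       iterations = length(wcss_trace), wcss_trace = wcss_trace,
       k_effective = k, merged = merged)
}

#' Phase 1: select the number of regions
#'
#' For each candidate k in `[k_min, k_max]` builds the refined k-class
#' intensity partition (quantile-initialized Lloyd reassignment on the
#' histogram) and scores it with the weighted fitness
#' `weight_x * norm(between-class variance) + weight_y * norm(1 - mean intraclass correlation)`,
#' both terms min-max normalized over the sweep. The smallest k scoring
#' within `plateau_tol` of the sweep maximum is returned (plateau
#' tie-break). Deterministic for a fixed seed.
#'
#' @param img numeric intensity matrix.
#' @param cfg a [haris_config()].
#' @return list with `k` and `diagnostics` (data frame: one row per
#'   candidate with the raw and normalized terms and the score).
#' @export
select_k <- function(img, cfg = haris_config()) {
  assert_gray(img)
  hist <- image_histogram(img)
  n_distinct <- sum(hist > 0)
  k_min <- cfg$k_min; k_max <- min(cfg$k_max, 255L)
  if (n_distinct < k_min) {
    warning(sprintf("image has %d distinct intensities < k_min = %d; clamping",
                    n_distinct, k_min))
    k_sel <- max(n_distinct, 1L)
    return(list(k = k_sel,
                diagnostics = data.frame(k = k_sel, between_var = NA,
                                         homogeneity = NA, score = NA)))
  }
  k_max <- min(k_max, n_distinct)
  ks <- k_min:k_max
  p <- hist / sum(hist)
  i <- 0:255
  mu_all <- sum(i * p)
  var_all <- sum(p * (i - mu_all)^2)

  rows <- lapply(ks, function(k) {
    km <- suppressWarnings(histogram_kmeans(hist, k, cfg$max_iterations))
    asg <- km$level_assign
    stats_k <- vapply(seq_len(km$k_effective), function(j) {
      m <- asg == j & hist > 0
      w <- sum(p[m])
      mu <- sum(i[m] * p[m]) / w
      v <- sum(p[m] * (i[m] - mu)^2) / w
      c(w = w, mu = mu, v = v)
    }, numeric(3))
    between <- sum(stats_k["w", ] * (stats_k["mu", ] - mu_all)^2)
    icorl <- vapply(seq_len(ncol(stats_k)), function(j)
      intraclass_correlation(sqrt(stats_k["v", j]), sqrt(var_all)), numeric(1))
    data.frame(k = k, between_var = between,
               homogeneity = 1 - mean(icorl))
  })
  diag <- do.call(rbind, rows)
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(1, length(x)) else (x - rng[1]) / diff(rng)
  }
  diag$sep_norm <- norm01(diag$between_var)
  diag$hom_norm <- norm01(diag$homogeneity)
  wsum <- cfg$weight_x + cfg$weight_y
  diag$score <- (cfg$weight_x * diag$sep_norm + cfg$weight_y * diag$hom_norm) / wsum
  top <- max(diag$score)
  k_sel <- diag$k[which(diag$score >= top - cfg$plateau_tol)[1]]
  list(k = k_sel, diagnostics = diag)
}

#' Phase 2: assemble pixels into k intensity regions
#'
#' Quantile-initialized Lloyd reassignment on the 256-bin histogram; labels
#' 1..k are ordered by ascending region mean. Each region's local-best
#' feature pixel is the member whose intensity minimizes the mean absolute
#' deviation to the region (the region median), first in row-major order on
#' ties. Regions are intensity classes and may be spatially disconnected.
#'
#' @param img numeric intensity matrix.
#' @param k number of regions (1..255).
#' @param cfg a [haris_config()].
#' @return list with `labels` (integer matrix 1..k), `stats` (data frame:
#'   label, pixel_count, mean, sd, best_row, best_col, best_intensity) and
#'   `wcss_trace` (non-increasing within-class squared deviation per
#'   iteration).
#' @export
haris_segment <- function(img, k, cfg = haris_config()) {
  assert_gray(img)
  if (k < 1 || k > 255) stop("k must lie in 1..255", call. = FALSE)
  hist <- image_histogram(img)
  km <- histogram_kmeans(hist, k, cfg$max_iterations)
  ints <- as.integer(round(clip255(img)))
  labels <- matrix(km$level_assign[ints + 1L], nrow(img), ncol(img))
  stats_df <- do.call(rbind, lapply(seq_len(km$k_effective), function(j) {
    m <- labels == j
    v <- img[m]
    med <- stats::median(v)
    # local-best feature: member intensity closest to the region median
    idx <- which(m)
    best <- idx[which.min(abs(img[idx] - med))]
    rc <- arrayInd(best, dim(img))
    data.frame(label = j, pixel_count = length(v), mean = mean(v),
               sd = if (length(v) < 2) 0 else stats::sd(v),
               best_row = rc[1] - 1L, best_col = rc[2] - 1L,
               best_intensity = img[best])
  }))
  list(labels = labels, stats = stats_df, wcss_trace = km$wcss_trace,
       k_effective = km$k_effective)
}
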