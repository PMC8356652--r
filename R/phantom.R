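# Synthetic brain-slice phantoms: dark background, bright skull annulus,
# mid-intensity parenchyma, and one or more bright tumor blobs with an
# optional enhancement rim. Geometry is circles/annuli so exact pixel-count
# oracles stay trivial; every generator is seeded and bit-reproducible.

PHANTOM_CLASSES <- c(background = 0L, skull = 1L, brain = 2L,
                     tumor_core = 3L, enhancement_rim = 4L)

#' Specification of a synthetic brain-slice phantom
#'
#' @param height,width image size in pixels.
#' @param skull_radius_frac outer skull radius as a fraction of the minimum
#'   dimension (half-extent).
#' @param skull_thickness annulus thickness in pixels.
#' @param background_mean,skull_mean,brain_mean,tumor_mean,rim_mean class
#'   intensities on the 0-255 scale; the rim is only drawn when
#'   `enhancement_rim > 0`.
#' @param noise_sd additive Gaussian noise SD (intensity units, >= 0).
#' @param n_tumors number of tumor blobs (>= 0).
#' @param tumor_radius_range length-2 numeric, min/max tumor radius (pixels).
#' @param enhancement_rim rim width in pixels (0 disables the rim class).
#' @param seed integer seed; same spec + seed gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128, width = 128,
                         skull_radius_frac = 0.45, skull_thickness = 4,
                         background_mean = 10, skull_mean = 220,
                         brain_mean = 110, tumor_mean = 190, rim_mean = 240,
                         noise_sd = 5, n_tumors = 1,
                         tumor_radius_range = c(8, 16),
                         enhancement_rim = 0, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               skull_radius_frac = skull_radius_frac,
               skull_thickness = skull_thickness,
               background_mean = background_mean, skull_mean = skull_mean,
               brain_mean = brain_mean, tumor_mean = tumor_mean,
               rim_mean = rim_mean, noise_sd = noise_sd,
               n_tumors = as.integer(n_tumors),
               tumor_radius_range = as.numeric(tumor_radius_range),
               enhancement_rim = enhancement_rim, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  means <- c(spec$background_mean, spec$skull_mean, spec$brain_mean,
             spec$tumor_mean, spec$rim_mean)
  if (any(means < 0 | means > 255))
    stop("phantom_spec: all class means must lie in [0, 255]", call. = FALSE)
  if (spec$noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (spec$n_tumors < 0) stop("phantom_spec: n_tumors must be >= 0", call. = FALSE)
  if (spec$height < 16 || spec$width < 16)
    stop("phantom_spec: image must be at least 16x16", call. = FALSE)
  if (spec$skull_radius_frac <= 0 || spec$skull_radius_frac > 0.5)
    stop("phantom_spec: skull_radius_frac must be in (0, 0.5]", call. = FALSE)
  if (spec$skull_thickness < 1)
    stop("phantom_spec: skull_thickness must be >= 1 pixel", call. = FALSE)
  r_outer <- spec$skull_radius_frac * min(spec$height, spec$width)
  r_inner <- r_outer - spec$skull_thickness
  if (r_inner <= 2)
    stop("phantom_spec: skull annulus leaves no brain interior", call. = FALSE)
  if (any(spec$tumor_radius_range <= 0) ||
      spec$tumor_radius_range[1] > spec$tumor_radius_range[2])
    stop("phantom_spec: tumor_radius_range must be positive and ordered", call. = FALSE)
  max_fit <- r_inner - spec$enhancement_rim - 2
  if (spec$n_tumors > 0 && spec$tumor_radius_range[2] >= max_fit)
    stop(sprintf(paste0("phantom_spec: tumor radius %.1f does not fit inside the ",
                        "brain interior (max %.1f)"),
         spec$tumor_radius_range[2], max_fit), call. = FALSE)
  invisible(spec)
}

#' Generate a synthetic brain-slice phantom with exact ground truth
#'
#' Draws the class geometry (background 0, skull 1, brain 2, tumor core 3,
#' enhancement rim 4), paints class mean intensities, adds clipped Gaussian
#' noise and rounds to 8 bit. The returned truth labels are the noise-free
#' geometry. Identical `(spec, seed)` gives bit-identical output; the global
#' RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth` list with `image` (numeric matrix, 0-255),
#'   `labels` (integer matrix, class ids above), `spec`, and `tumors`
#'   (matrix of drawn centers and radii: row, col, radius).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r_outer <- spec$skull_radius_frac * min(h, w)
  r_inner <- r_outer - spec$skull_thickness
  dist <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))

  labels <- matrix(PHANTOM_CLASSES[["background"]], h, w)
  labels[dist <= r_outer] <- PHANTOM_CLASSES[["skull"]]
  labels[dist <= r_inner] <- PHANTOM_CLASSES[["brain"]]

  rim_w <- spec$enhancement_rim
  centers <- matrix(numeric(0), 0, 3) # row, col, radius
  if (spec$n_tumors > 0) {
    placed <- 0L
    attempts <- 0L
    while (placed < spec$n_tumors && attempts < 500L) {
      attempts <- attempts + 1L
      r <- stats::runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
      max_c <- r_inner - r - rim_w - 1
      if (max_c <= 0) break
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * max_c
      ty <- cy + rad * sin(ang); tx <- cx + rad * cos(ang)
      if (placed > 0) {
        sep <- sqrt((centers[, 1] - ty)^2 + (centers[, 2] - tx)^2)
        if (any(sep < centers[, 3] + r + rim_w + 2)) next
      }
      centers <- rbind(centers, c(ty, tx, r))
      placed <- placed + 1L
    }
    if (placed < spec$n_tumors)
      stop("generate_phantom: could not place all tumors inside the brain mask",
           call. = FALSE)
    for (i in seq_len(nrow(centers))) {
      d_t <- sqrt(outer((seq_len(h) - centers[i, 1])^2,
                        (seq_len(w) - centers[i, 2])^2, `+`))
      if (rim_w > 0) {
        rim_px <- d_t <= centers[i, 3] + rim_w &
          labels == PHANTOM_CLASSES[["brain"]]
        labels[rim_px] <- PHANTOM_CLASSES[["enhancement_rim"]]
      }
      labels[d_t <= centers[i, 3]] <- PHANTOM_CLASSES[["tumor_core"]]
    }
  }

  means <- c(spec$background_mean, spec$skull_mean, spec$brain_mean,
             spec$tumor_mean, spec$rim_mean)
  img <- matrix(means[labels + 1L], h, w)
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  img <- round(clip255(img))

  colnames(centers) <- c("row", "col", "radius")
  structure(list(image = img, labels = labels, spec = spec, tumors = centers),
            class = "phantom_truth")
}

#' Seeded suite of jittered phantoms
#'
#' Draws `n` phantoms whose tumor count, size and contrast are jittered from
#' `base` by a single seeded stream: tumor mean +-10 intensity units, radius
#' bounds resampled inside the base range, and a 30% chance of a second
#' tumor. Reproducible as a whole for a fixed `seed`.
#'
#' @param n number of phantoms (>= 1).
#' @param base a [phantom_spec()] providing the study conditions.
#' @param seed integer seed for the jitter stream.
#' @return list of `phantom_truth` objects.
#' @export
phantom_suite <- function(n, base = phantom_spec(), seed = 1L) {
  if (n < 1) stop("phantom_suite: n must be >= 1", call. = FALSE)
  validate_phantom_spec(base)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      sp <- base
      sp$seed <- as.integer(stats::runif(1, 1, 2^30))
      sp$tumor_mean <- clip255(base$tumor_mean + stats::runif(1, -10, 10))
      lo <- stats::runif(1, base$tumor_radius_range[1],
                         mean(base$tumor_radius_range))
      hi <- stats::runif(1, lo, base$tumor_radius_range[2])
      sp$tumor_radius_range <- c(lo, hi)
      sp$n_tumors <- base$n_tumors +
        (stats::runif(1) < 0.3 && base$n_tumors > 0)
      generate_phantom(sp)
    })
  })
}

#' True class count of a phantom (distinct label classes present)
#' @param truth a `phantom_truth`.
#' @return integer count of distinct classes in the truth labels.
#' @export
phantom_class_count <- function(truth) {
  length(unique(as.integer(truth$labels)))
}

#' Whole-tumor truth mask (core plus enhancement rim)
#' @param truth a `phantom_truth`.
#' @return logical matrix.
#' @export
phantom_tumor_mask <- function(truth) {
  truth$labels == PHANTOM_CLASSES[["tumor_core"]] |
    truth$labels == PHANTOM_CLASSES[["enhancement_rim"]]
}
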