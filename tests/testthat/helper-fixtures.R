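# Shared fixtures, built once per test run. Phantoms follow the study
# conditions (128x128, noise SD 5, one tumor radius 8-16); small variants
# keep per-file tests fast.

std_spec <- function(...) phantom_spec(...)

small_spec <- function(...) {
  phantom_spec(height = 64, width = 64, tumor_radius_range = c(5, 8), ...)
}

# memoised heavy fixtures
.fix <- new.env()

fix_phantom_noisy <- function() {
  if (is.null(.fix$noisy)) .fix$noisy <- generate_phantom(std_spec(seed = 7))
  .fix$noisy
}

fix_phantom_clean <- function() {
  if (is.null(.fix$clean)) {
    s <- fix_phantom_noisy()$spec; s$noise_sd <- 0
    .fix$clean <- generate_phantom(s)
  }
  .fix$clean
}

fix_filtered <- function() {
  if (is.null(.fix$filtered))
    .fix$filtered <- adaptive_bilateral_filter(fix_phantom_noisy()$image)
  .fix$filtered
}

# seeded random histogram over a few intensity modes
random_histogram <- function(seed) {
  withr::with_seed(seed, {
    n_modes <- sample(2:4, 1)
    means <- sort(sample(20:235, n_modes))
    sds <- runif(n_modes, 3, 12)
    wts <- runif(n_modes, 0.1, 1)
    vals <- unlist(lapply(seq_len(n_modes), function(i)
      round(rnorm(round(3000 * wts[i]), means[i], sds[i]))))
    tabulate(pmin(pmax(vals, 0), 255) + 1L, 256L)
  })
}

# an interior pixel of the tumor core (max erosion depth), as (row, col)
tumor_interior_pixel <- function(truth, depth = 3) {
  core <- truth$labels == 3
  er <- core
  for (i in seq_len(depth)) {
    er <- er & slns:::shift_pad(er, 1, 0) & slns:::shift_pad(er, -1, 0) &
      slns:::shift_pad(er, 0, 1) & slns:::shift_pad(er, 0, -1)
    if (!any(er)) break
  }
  pick <- if (any(er)) er else core
  arrayInd(which(pick)[1], dim(truth$labels))
}
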