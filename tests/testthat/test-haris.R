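test_that("the plug-in fitness matches hand evaluation", {
  cfg1 <- haris_config(weight_x = 1, weight_y = 1)
  expect_equal(haris_objective(list(total_pixels = 100, pixels_in_segment = 10,
                                    segment_sd_term = 5, region_count = 5), cfg1),
               11)
  cfg2 <- haris_config(weight_x = 2, weight_y = 3)
  expect_equal(haris_objective(list(total_pixels = 256, pixels_in_segment = 16,
                                    segment_sd_term = 8, region_count = 4), cfg2),
               38)
  # degenerate weight: reduces to x * Tot / pix_seg exactly
  cfgx <- haris_config(weight_x = 1.5, weight_y = 0)
  expect_equal(haris_objective(list(total_pixels = 90, pixels_in_segment = 9,
                                    segment_sd_term = 99, region_count = 7), cfgx),
               1.5 * 90 / 9)
  expect_error(haris_objective(list(total_pixels = 10, pixels_in_segment = 0,
                                    segment_sd_term = 1, region_count = 2), cfg1),
               "positive")
})

test_that("with y = 0 the fitness strictly decreases as segments grow", {
  cfg <- haris_config(weight_x = 1, weight_y = 0)
  vals <- vapply(c(5, 10, 20, 50), function(px)
    haris_objective(list(total_pixels = 100, pixels_in_segment = px,
                         segment_sd_term = 1, region_count = 2), cfg), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("region-count selection recovers the class count of a clean phantom", {
  ph <- generate_phantom(std_spec(noise_sd = 0, seed = 3))
  sel <- select_k(ph$image, haris_config(k_min = 2, k_max = 8))
  expect_equal(sel$k, 4)
  expect_true(all(c("between_var", "homogeneity", "score") %in%
                    names(sel$diagnostics)))
})

test_that("constant images clamp the region count with a warning", {
  img <- matrix(50, 32, 32)
  expect_warning(sel <- select_k(img, haris_config(k_min = 2, k_max = 8)),
                 "clamping")
  expect_equal(sel$k, 1)
})

test_that("segmentation labels every pixel and respects k", {
  ph <- fix_phantom_noisy()
  seg <- haris_segment(ph$image, 4, haris_config(k_min = 2, k_max = 8))
  expect_true(all(seg$labels %in% 1:4))
  expect_equal(sort(unique(as.integer(seg$labels))), 1:4)
  expect_equal(sum(seg$stats$pixel_count), length(ph$image))
})

test_that("a single region reproduces the global statistics", {
  ph <- fix_phantom_noisy()
  seg <- haris_segment(ph$image, 1)
  expect_equal(unique(as.integer(seg$labels)), 1L)
  expect_equal(seg$stats$sd, sd(as.numeric(ph$image)))
  expect_equal(seg$stats$mean, mean(ph$image))
})

test_that("a two-value image splits exactly at its two values", {
  img <- matrix(0, 20, 20); img[1:10, ] <- 255
  seg <- haris_segment(img, 2)
  expect_true(all(seg$labels[img == 0] == 1))
  expect_true(all(seg$labels[img == 255] == 2))
})

test_that("a clean 4-class phantom is segmented exactly (best-match Dice 1)", {
  ph <- generate_phantom(std_spec(noise_sd = 0, seed = 13))
  seg <- haris_segment(ph$image, 4)
  bmd <- slns:::best_match_dice(seg$labels, ph$labels)
  expect_equal(unname(bmd), rep(1, 4))
})

test_that("the reassignment loop never increases the within-class deviation", {
  for (s in 1:5) {
    ph <- generate_phantom(small_spec(noise_sd = 15, seed = s))
    seg <- haris_segment(ph$image, 5)
    expect_true(all(diff(seg$wcss_trace) <= 1e-9), info = paste("seed", s))
  }
})

test_that("k above the distinct intensity count merges centroids with a warning", {
  img <- matrix(rep(c(0, 100, 200), length.out = 144), 12, 12)
  expect_warning(seg <- haris_segment(img, 5), "distinct")
  expect_equal(seg$k_effective, 3)
})

test_that("each region's best feature pixel belongs to it and tracks the median", {
  ph <- fix_phantom_noisy()
  seg <- haris_segment(ph$image, 4)
  for (i in seq_len(nrow(seg$stats))) {
    st <- seg$stats[i, ]
    expect_equal(seg$labels[st$best_row + 1, st$best_col + 1], st$label)
    v <- ph$image[seg$labels == st$label]
    expect_equal(abs(st$best_intensity - median(v)), min(abs(v - median(v))))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(haris_config(weight_x = 0, weight_y = 0), "not both 0")
  expect_error(haris_config(k_min = 10, k_max = 5), "k_min")
  expect_equal(haris_config()$k_min, 23L)  # field prior for full-scale slices
  expect_error(haris_segment(fix_phantom_noisy()$image, 0), "1..255")
})
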