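test_that("ASSI of identical windows equals the noise-confidence factor", {
  w <- matrix(c(10, 50, 90, 130, 170, 210, 30, 70, 110), 3, 3)
  cfg <- assi_config(sigma_e = 4)
  v <- var(as.numeric(w)) * 8 / 9          # population variance
  expect_equal(assi(w, w, cfg), v / (v + 8))
  # sigma_e = 0 degenerates omega to 1
  expect_equal(assi(w, w, assi_config(sigma_e = 0)), 1)
})

test_that("two flat windows with noise present score zero", {
  a <- matrix(80, 3, 3); b <- matrix(80, 3, 3)
  expect_equal(assi(a, b, assi_config(sigma_e = 3)), 0)
})

test_that("ASSI is symmetric when the noise factor is degenerate", {
  for (s in 1:10) {
    pq <- withr::with_seed(s, list(matrix(runif(9, 0, 255), 3, 3),
                                   matrix(runif(9, 0, 255), 3, 3)))
    cfg <- assi_config(sigma_e = 0)
    expect_equal(assi(pq[[1]], pq[[2]], cfg), assi(pq[[2]], pq[[1]], cfg))
  }
})

test_that("window shape mismatches are rejected", {
  expect_error(assi(matrix(1, 3, 3), matrix(1, 5, 5), assi_config(sigma_e = 1)),
               "identical shapes")
})

test_that("threshold extremes give empty and full masks and masks nest", {
  ph <- fix_phantom_noisy()
  filt <- fix_filtered()
  rc <- tumor_interior_pixel(ph)
  ref <- slns:::extract_patch(filt, rc[1], rc[2], 3)
  empty <- classify_pixels(filt, ref, assi_config(ci_threshold = Inf), "pixel")
  expect_equal(sum(empty), 0)
  full <- classify_pixels(filt, ref, assi_config(ci_threshold = -Inf), "pixel")
  expect_equal(sum(full), length(filt))
  masks <- lapply(c(0.2, 0.5, 0.8), function(t)
    classify_pixels(filt, ref, assi_config(ci_threshold = t), "pixel"))
  expect_true(all(masks[[2]][masks[[3]]]))   # higher-threshold mask is a subset
  expect_true(all(masks[[1]][masks[[2]]]))
})

test_that("a missing reference points the user at the bootstrap rule", {
  expect_error(classify_pixels(fix_filtered(), NULL), "bootstrap")
})

test_that("per-pixel correlation-index sweep recovers the tumor mask", {
  # sweep oracle against generator truth; mean over seeded phantoms
  scores <- vapply(1:5, function(s) {
    ph <- generate_phantom(std_spec(seed = s * 7))
    filt <- adaptive_bilateral_filter(ph$image)
    seg <- haris_segment(filt, 4, haris_config(k_min = 2, k_max = 8))
    bm <- brain_mask(seg)
    rc <- tumor_interior_pixel(ph)
    ref <- slns:::extract_patch(filt, rc[1], rc[2], 3)
    m <- classify_pixels(filt, ref, assi_config(ci_threshold = 0.5), "pixel",
                         roi = bm)
    ci <- attr(m, "ci")
    tm <- phantom_tumor_mask(ph)
    max(vapply(seq(0.05, 0.99, by = 0.005),
               function(t) dice(ci > t & bm, tm), numeric(1)))
  }, numeric(1))
  expect_gte(mean(scores), 0.85)
})

test_that("fuzzy assignment and vertex update match their closed forms", {
  expect_equal(fuzzy_membership_assign(100, 80, 0), 80)
  expect_equal(fuzzy_membership_assign(77, 77, 0.63), 77)
  expect_equal(fuzzy_membership_assign(100, 80, 0.5), 60)
  expect_equal(fuzzy_vertex_update(100, 80, 0), 80)
  expect_equal(fuzzy_vertex_update(55, 55, 0.4), 55)
  expect_equal(fuzzy_vertex_update(60, 80, 0.5), 100)
  expect_error(fuzzy_membership_assign(10, 5, 1), "< 1")
  expect_error(fuzzy_vertex_update(10, 5, 1.2), "< 1")
})

test_that("assignment then update with mem = 0 is the identity pair", {
  v <- 140; inst <- 95
  expect_equal(fuzzy_membership_assign(v, inst, 0), inst)
  expect_equal(fuzzy_vertex_update(v, v, 0), v)
})

test_that("fuzzy refinement keeps a valid partition and sane vertices", {
  ph <- fix_phantom_noisy()
  seg <- haris_segment(fix_filtered(), 4)
  fz <- fuzzy_segment_refine(fix_filtered(), seg, iterations = 3)
  expect_true(all(fz$labels %in% seq_along(fz$vertices)))
  expect_true(all(fz$vertices >= 0 & fz$vertices <= 255))
  expect_true(all(fz$membership >= 0 & fz$membership < 1))
})
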