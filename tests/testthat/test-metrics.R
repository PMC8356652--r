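test_that("confusion counts cover every pixel and match hand enumeration", {
  truth <- matrix(c(1, 1, 0, 0,
                    1, 1, 0, 0,
                    0, 0, 0, 0,
                    0, 0, 0, 1), 4, 4, byrow = TRUE) == 1
  pred <- matrix(c(1, 0, 0, 0,
                   1, 1, 1, 0,
                   0, 0, 0, 0,
                   0, 0, 0, 0), 4, 4, byrow = TRUE) == 1
  cc <- confusion(pred, truth)
  # cell-by-cell: TP at (1,1),(2,1),(2,2); FP at (2,3); FN at (1,2),(4,4)
  expect_equal(cc, list(TP = 3L, TN = 10L, FP = 1L, FN = 2L))
  expect_equal(with(cc, TP + TN + FP + FN), 16L)
  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0L)
  inv <- confusion(!truth, truth)
  expect_equal(inv$TP + inv$TN, 0L)
  expect_error(confusion(pred, truth[1:3, ]), "dimensions")
})

test_that("the metric report matches hand-worked formulas", {
  r <- metric_report(list(TP = 40, TN = 40, FP = 10, FN = 10))
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$jsi, 40 / 60)
  expect_equal(r$mcc, (1600 - 100) / 2500)
  perfect <- metric_report(list(TP = 25, TN = 75, FP = 0, FN = 0))
  expect_equal(unname(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                       "jsi", "mcc")])), rep(1, 5))
})

test_that("complementing the prediction flips the sign of the correlation", {
  truth <- matrix(rep(c(TRUE, FALSE), 50), 10, 10)
  pred <- truth; pred[1:3, 1] <- !pred[1:3, 1]
  m1 <- metric_report(confusion(pred, truth))$mcc
  m2 <- metric_report(confusion(!pred, truth))$mcc
  expect_equal(m1, -m2)
  expect_gt(m1, 0)
})

test_that("accuracy decomposes over the class-weighted rates", {
  for (s in 1:10) {
    cc <- withr::with_seed(s, as.list(setNames(sample(1:200, 4),
                                               c("TP", "TN", "FP", "FN"))))
    r <- metric_report(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(r$accuracy, (r$sensitivity * P + r$specificity * N) / (P + N))
    precision <- cc$TP / (cc$TP + cc$FP)
    expect_lte(r$jsi, r$sensitivity)
    expect_lte(r$jsi, precision)
  }
})

test_that("independence tables have zero correlation", {
  for (cc in list(list(TP = 10, TN = 20, FP = 10, FN = 20),
                  list(TP = 6, TN = 4, FP = 12, FN = 2))) {
    expect_equal(cc$TP * cc$TN, cc$FP * cc$FN)
    expect_equal(metric_report(cc)$mcc, 0)
  }
})

test_that("vanishing denominators are flagged, never silently zero", {
  r <- metric_report(list(TP = 0, TN = 50, FP = 0, FN = 0))
  expect_true(is.na(r$sensitivity))
  expect_true("sensitivity" %in% r$undefined)
  expect_error(metric_report(list(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")
})

test_that("tumor burden counts the phantom classes with wt = tc + et", {
  ph <- generate_phantom(phantom_spec(enhancement_rim = 2, seed = 4))
  b <- tumor_burden(ph$labels)
  expect_equal(b$wt_area, b$tc_area + b$et_area)
  expect_gt(b$et_area, 0)
  # disk oracle for the core area
  cy <- ph$tumors[1, "row"]; cx <- ph$tumors[1, "col"]; r <- ph$tumors[1, "radius"]
  d <- sqrt(outer((seq_len(128) - cy)^2, (seq_len(128) - cx)^2, `+`))
  expect_equal(b$tc_area, sum(d <= r))
  empty <- matrix(2L, 8, 8)
  expect_equal(tumor_burden(empty), list(tc_area = 0L, et_area = 0L, wt_area = 0L))
  expect_error(tumor_burden(matrix(9L, 4, 4)), "unknown label")
})
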