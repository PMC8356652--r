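test_that("the cost is half the squared error and permutation-invariant", {
  expect_equal(net_cost(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(net_cost(c(3, 4), c(0, 0)), 12.5)
  a <- c(2, -1, 7); b <- c(0, 3, 5)
  expect_equal(net_cost(a, b), net_cost(rev(a), rev(b)))
  expect_error(net_cost(1:3, 1:2), "lengths differ")
})

test_that("the rectifier clips negatives and is idempotent", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(5), 5)
  x <- c(-2, 0, 3.5, -0.1)
  expect_equal(relu(relu(x)), relu(x))
})

test_that("layer errors follow the chain rule through the rectifier", {
  w <- diag(3)
  expect_equal(layer_error(w, c(1, 2, 3), c(-1, -2, -3)), c(0, 0, 0))
  expect_equal(layer_error(w, c(1, 2, 3), c(1, 2, 3)), c(1, 2, 3))
  expect_error(layer_error(matrix(1, 2, 2), c(1, 2, 3), c(1, 2)), "chain")
})

test_that("backpropagation matches central-difference gradients", {
  for (s in 1:10) {
    net <- tinynet_init(6, 4, 2, seed = s)
    xy <- withr::with_seed(s + 50, list(matrix(runif(6, -1, 1), 6, 1),
                                        matrix(runif(2), 2, 1)))
    x <- xy[[1]]; y <- xy[[2]]
    g <- slns:::tinynet_grad(net, x, y)
    eps <- 1e-6
    for (par in c("W1", "b1", "W2", "b2")) {
      idx <- seq_along(net[[par]])
      fd <- vapply(idx, function(i) {
        up <- net; up[[par]][i] <- up[[par]][i] + eps
        dn <- net; dn[[par]][i] <- dn[[par]][i] - eps
        (net_cost(slns:::tinynet_forward(up, x)$out, y) -
           net_cost(slns:::tinynet_forward(dn, x)$out, y)) / (2 * eps)
      }, numeric(1))
      bp <- as.numeric(g[[paste0("d", par)]])
      denom <- pmax(abs(fd), abs(bp), 1e-8)
      expect_lt(max(abs(fd - bp) / denom), 1e-5)
    }
  }
})

make_separable_patches <- function(n = 40) {
  withr::with_seed(17, {
    dark <- lapply(seq_len(n / 2), function(i) matrix(runif(9, 0, 60), 3, 3))
    bright <- lapply(seq_len(n / 2), function(i) matrix(runif(9, 180, 255), 3, 3))
    list(patches = c(dark, bright), labels = rep(1:2, each = n / 2))
  })
}

test_that("a separable two-class patch set is learned perfectly", {
  d <- make_separable_patches()
  model <- train_patch_classifier(d$patches, d$labels, epochs = 200,
                                  learning_rate = 0.05, seed = 1)
  pred <- predict_patches(model, d$patches)
  expect_equal(mean(pred == d$labels), 1)
  expect_lt(model$loss_trace[length(model$loss_trace)], model$loss_trace[1])
})

test_that("training is deterministic and zero epochs keep the initialization", {
  d <- make_separable_patches()
  m1 <- train_patch_classifier(d$patches, d$labels, epochs = 50, seed = 9)
  m2 <- train_patch_classifier(d$patches, d$labels, epochs = 50, seed = 9)
  expect_identical(m1$net, m2$net)
  m0 <- train_patch_classifier(d$patches, d$labels, epochs = 0, seed = 9)
  expect_identical(m0$net, tinynet_init(9, 16, 2, seed = 9))
  expect_error(train_patch_classifier(d$patches, rep(1, length(d$patches))),
               "two classes")
})

test_that("the experience store is append-only with running-mean priors", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  expect_null(experience_prior(store))
  patch <- matrix(0:8 * 20, 3, 3)
  experience_update(store, list(run_id = "a", k = 4, fet_threshold = 120,
                                reference_patch = patch))
  expect_equal(length(experience_read(store)), 1)
  # fractional texture at the store's 1/100 precision survives the round trip
  patch2 <- patch + 1.07
  experience_update(store, list(run_id = "b", k = 6, fet_threshold = 140,
                                reference_patch = patch2))
  prior <- experience_prior(store)
  expect_equal(prior$k_prior, 5)
  expect_equal(prior$threshold_prior, 130)
  expect_equal(prior$n_records, 2)
  expect_equal(prior$reference_patch, patch2)
})

test_that("a corrupted store is rejected with recovery instructions", {
  store <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c("{\"run_id\":\"a\",\"k\":4}", "not json {"), store)
  expect_error(experience_read(store), "corrupted at line 2")
  expect_error(experience_update(store, list(run_id = "x")), "lacks fields")
})
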