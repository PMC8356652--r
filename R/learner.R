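# Self-learning layer: a small dense rectifier network on fixed-size
# patches (squared-error cost, backpropagated layer errors, plain gradient
# descent) plus an append-only experience store whose records (chosen k,
# threshold, class profile, reference patch) warm-start later runs.

#' Squared-error cost
#'
#' `||prediction - target||^2 / 2`.
#'
#' @param prediction,target equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
net_cost <- function(prediction, target) {
  if (length(prediction) != length(target))
    stop("prediction and target lengths differ", call. = FALSE)
  sum((prediction - target)^2) / 2
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`.
#'
#' @param x numeric vector or matrix.
#' @return same shape, negative entries zeroed.
#' @export
relu <- function(x) pmax(x, 0)

relu_grad <- function(x) as.numeric(x > 0)

#' Backpropagated error at a layer
#'
#' `(W^l)^T e^{l+1} * f'(x^l)` with `f'` the rectifier derivative (0 for
#' negative pre-activations, 1 for positive).
#'
#' @param w_l weight matrix of layer l (rows = units of l+1, cols = units of l).
#' @param e_next error vector at layer l+1.
#' @param x_l pre-activation vector at layer l.
#' @return error vector at layer l.
#' @export
layer_error <- function(w_l, e_next, x_l) {
  if (nrow(w_l) != length(e_next) || ncol(w_l) != length(x_l))
    stop("layer shapes do not chain", call. = FALSE)
  as.numeric(crossprod(w_l, e_next)) * relu_grad(x_l)
}

#' Initialize tiny network parameters
#'
#' One rectified hidden layer, linear output; small uniform weights drawn
#' from a local seeded stream.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param seed integer seed.
#' @return `tinynet` list with `W1`, `b1`, `W2`, `b2`.
#' @export
tinynet_init <- function(n_in, n_hidden = 16L, n_out = 2L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    structure(list(
      W1 = matrix(stats::runif(n_hidden * n_in, -0.1, 0.1), n_hidden, n_in),
      b1 = rep(0, n_hidden),
      W2 = matrix(stats::runif(n_out * n_hidden, -0.1, 0.1), n_out, n_hidden),
      b2 = rep(0, n_out)), class = "tinynet")
  })
}

# forward pass; X is n_in x n_samples
tinynet_forward <- function(net, X) {
  Z1 <- net$W1 %*% X + net$b1
  A1 <- relu(Z1)
  Z2 <- net$W2 %*% A1 + net$b2
  list(Z1 = Z1, A1 = A1, out = Z2)
}

# mean cost and parameter gradients over a batch (squared error / 2,
# averaged; errors propagated with layer_error through the hidden layer)
tinynet_grad <- function(net, X, Y) {
  n <- ncol(X)
  fw <- tinynet_forward(net, X)
  E2 <- fw$out - Y                           # output-layer error (linear)
  E1 <- (t(net$W2) %*% E2) * (fw$Z1 > 0)     # layer_error, vectorized
  list(cost = sum(E2^2) / (2 * n),
       dW2 = (E2 %*% t(fw$A1)) / n, db2 = rowSums(E2) / n,
       dW1 = (E1 %*% t(X)) / n, db1 = rowSums(E1) / n)
}

#' Train the patch classifier
#'
#' Plain gradient descent on the squared-error cost with backpropagated
#' rectifier errors. Inputs are flattened patches scaled to \[0, 1\];
#' targets are one-hot class indicators. Deterministic given the seed;
#' `epochs = 0` returns the initialization unchanged.
#'
#' @param patches list of equal-size numeric matrices (0-255 scale).
#' @param labels integer class labels (>= 2 distinct classes required).
#' @param epochs full-batch gradient steps.
#' @param learning_rate step size.
#' @param n_hidden hidden-layer width.
#' @param seed integer seed for initialization.
#' @return a `patch_classifier` list with the `tinynet`, class levels,
#'   patch dimensions and the per-epoch training loss trace.
#' @export
train_patch_classifier <- function(patches, labels, epochs = 200L,
                                   learning_rate = 0.01, n_hidden = 16L,
                                   seed = 1L) {
  lv <- sort(unique(labels))
  if (length(lv) < 2)
    stop("training needs at least two classes", call. = FALSE)
  if (length(patches) != length(labels))
    stop("patches and labels lengths differ", call. = FALSE)
  dims <- dim(patches[[1]])
  X <- vapply(patches, function(p) as.numeric(p) / 255, numeric(prod(dims)))
  Y <- vapply(labels, function(l) as.numeric(lv == l), numeric(length(lv)))
  net <- tinynet_init(nrow(X), n_hidden, length(lv), seed)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    g <- tinynet_grad(net, X, Y)
    trace[e] <- g$cost
    net$W1 <- net$W1 - learning_rate * g$dW1
    net$b1 <- net$b1 - learning_rate * g$db1
    net$W2 <- net$W2 - learning_rate * g$dW2
    net$b2 <- net$b2 - learning_rate * g$db2
  }
  structure(list(net = net, classes = lv, patch_dim = dims,
                 loss_trace = trace),
            class = "patch_classifier")
}

#' Predict patch classes
#'
#' @param model a [train_patch_classifier()] result.
#' @param patches list of patches with the training dimensions.
#' @return vector of predicted class labels.
#' @export
predict_patches <- function(model, patches) {
  X <- vapply(patches, function(p) as.numeric(p) / 255,
              numeric(prod(model$patch_dim)))
  out <- tinynet_forward(model$net, X)$out
  model$classes[max.col(t(out), ties.method = "first")]
}

# ---- experience store (append-only JSON lines) -----------------------------

# Patches are stored as base-16 payloads at 1/100 intensity precision
# (4 hex digits per pixel), so the sub-integer texture that the similarity
# index's noise-confidence factor relies on survives the round trip.
encode_patch <- function(patch, scale = 100L) {
  list(hex = paste(sprintf("%04x", as.integer(round(clip255(patch) * scale))),
                   collapse = ""),
       nrow = nrow(patch), ncol = ncol(patch), scale = scale)
}

decode_patch <- function(enc) {
  hx <- enc$hex
  scale <- if (is.null(enc$scale)) 100L else enc$scale
  vals <- strtoi(substring(hx, seq(1, nchar(hx), 4), seq(4, nchar(hx), 4)),
                 base = 16L)
  matrix(vals / scale, enc$nrow, enc$ncol)
}

#' Append a run record to the experience store
#'
#' The store is an append-only JSON-lines file; each record holds the run
#' id, chosen k, FET threshold, per-class intensity profile, the tumor
#' reference patch (hex-encoded) and a timestamp.
#'
#' @param store path to the store file (created if missing).
#' @param record list with `run_id`, `k`, `fet_threshold`, `class_profile`
#'   (data frame or list with mean/sd), `reference_patch` (matrix).
#' @return the store path, invisibly.
#' @export
experience_update <- function(store, record) {
  stopifnot(is.list(record))
  needed <- c("run_id", "k", "fet_threshold", "reference_patch")
  missing <- setdiff(needed, names(record))
  if (length(missing))
    stop("record lacks fields: ", paste(missing, collapse = ", "), call. = FALSE)
  rec <- list(run_id = record$run_id,
              k = record$k,
              fet_threshold = record$fet_threshold,
              class_profile = record$class_profile,
              reference_patch = encode_patch(record$reference_patch),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  con <- file(store, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(store)
}

#' Read the experience store
#'
#' @param store path to the JSON-lines store.
#' @return list of records (empty list when the file does not exist).
#' @export
experience_read <- function(store) {
  if (!file.exists(store)) return(list())
  lines <- readLines(store, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e)
               stop(sprintf(paste0("experience store '%s' is corrupted at line %d; ",
                                   "remove or repair that line (the store is ",
                                   "plain JSON-lines) and re-run"),
                            store, i), call. = FALSE))
  })
  recs
}

#' Warm-start prior from the experience store
#'
#' Running means of the stored k and FET threshold plus the most recent
#' reference patch. An empty store yields prior "none" (`NULL`) and the
#' pipeline runs cold.
#'
#' @param store path to the store.
#' @return `NULL` if the store is empty, else a list with `k_prior`,
#'   `threshold_prior`, `reference_patch`, `n_records`.
#' @export
experience_prior <- function(store) {
  recs <- experience_read(store)
  if (length(recs) == 0) return(NULL)
  ks <- vapply(recs, function(r) as.numeric(r$k), numeric(1))
  th <- vapply(recs, function(r) as.numeric(r$fet_threshold), numeric(1))
  list(k_prior = mean(ks),
       threshold_prior = mean(th),
       reference_patch = decode_patch(recs[[length(recs)]]$reference_patch),
       n_records = length(recs))
}
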