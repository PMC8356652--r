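# Independent exhaustive-scan oracles (plain double loops, no shared code
# with the implementation), used by the thresholding and acceptance tests.

oracle_fet <- function(counts) {
  p <- counts / sum(counts)
  best_t <- NA; best_v <- Inf
  for (t in 1:254) {
    v <- 0
    lo_mass <- sum(p[1:(t + 1)]); hi_mass <- sum(p[(t + 2):256])
    if (lo_mass == 0 || hi_mass == 0) next
    m0 <- sum((0:t) * p[1:(t + 1)]) / lo_mass
    m1 <- sum(((t + 1):255) * p[(t + 2):256]) / hi_mass
    for (i in 0:255) {
      if (p[i + 1] == 0) next
      mu <- if (i <= t) 1 / (1 + abs(i - m0) / 255) else 1 / (1 + abs(i - m1) / 255)
      mu <- min(max(mu, 1e-12), 1 - 1e-12)
      v <- v + p[i + 1] * (-mu * log2(mu) - (1 - mu) * log2(1 - mu))
    }
    if (v < best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

oracle_otsu <- function(counts) {
  p <- counts / sum(counts)
  best_t <- NA; best_v <- -1
  for (t in 1:254) {
    w1 <- sum(p[seq_len(t)]); w2 <- 1 - w1   # classes split at x < t
    if (w1 == 0 || w2 == 0) next
    mu1 <- sum((0:(t - 1)) * p[seq_len(t)]) / w1
    mu2 <- sum((t:255) * p[(t + 1):256]) / w2
    v <- w1 * w2 * (mu1 - mu2)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

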