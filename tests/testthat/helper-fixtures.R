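# Shared fixtures: tiny synthetic image sets and an exhaustive k-means oracle.

# Small well-separated synthetic set (in-memory pixels).
make_fixture <- function(n_majority = 120, n_minority = 8, n_modes = 3,
                         side = 24, noise_sd = 6, seed = 42) {
  generate_imbalanced_images(synthetic_spec(
    n_majority = n_majority, n_minority = n_minority, n_modes = n_modes,
    side = side, noise_sd = noise_sd, seed = seed))
}

# Exhaustive global SSE minimum over all assignments of n points to k
# clusters (empty clusters allowed; centers are cluster means).
brute_force_sse <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  a <- rep(1L, n)
  repeat {
    s <- 0
    for (j in unique(a)) {
      rows <- X[a == j, , drop = FALSE]
      ctr <- colMeans(rows)
      s <- s + sum(sweep(rows, 2, ctr)^2)
    }
    if (s < best) best <- s
    # next assignment in base-k counting
    i <- 1L
    while (i <= n) {
      a[i] <- a[i] + 1L
      if (a[i] <= k) break
      a[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# Deterministic gradient test image (smooth, full dynamic range).
gradient_image <- function(side = 24) {
  outer(seq_len(side), seq_len(side), function(r, c) (r + c)) /
    (2 * side) * 255
}
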