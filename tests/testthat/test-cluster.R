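test_that("sse matches hand-computed values and errors on bad input", {
  # two points straddling one centre: 1 + 1 = 2
  pts <- rbind(c(0, 0), c(2, 0))
  expect_equal(sse(pts, rbind(c(1, 0)), c(1L, 1L)), 2)
  # points equal to their assigned centres -> 0
  ctrs <- rbind(c(0, 0), c(5, 5))
  expect_equal(sse(rbind(c(0, 0), c(5, 5)), ctrs, c(1L, 2L)), 0)
  expect_error(sse(pts, rbind(c(1, 0, 0)), c(1L, 1L)), "dimensionality")
  expect_error(sse(pts, ctrs, c(1L, 3L)), "out of range")
})

test_that("the column mean minimizes single-cluster SSE", {
  withr::with_seed(1, X <- matrix(stats::rnorm(40), 10, 4))
  ctr <- colMeans(X)
  base <- sse(X, rbind(ctr), rep(1L, 10))
  for (i in 1:10) {
    perturbed <- rbind(ctr + stats::rnorm(4, sd = 0.2))
    expect_gte(sse(X, perturbed, rep(1L, 10)), base)
  }
})

test_that("kmeans saturation and degenerate k behave as closed forms", {
  withr::with_seed(2, X <- matrix(stats::rnorm(12), 6, 2))
  fit1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(as.vector(fit1$centers), colMeans(X))
  fitn <- kmeans_fit(X, nrow(X), seed = 1)
  expect_equal(fitn$sse, 0)
  expect_error(kmeans_fit(X, 0), ">= 1")
  expect_error(kmeans_fit(X, 7), "exceeds")
})

test_that("two well-separated blobs are recovered exactly (exhaustive oracle)", {
  withr::with_seed(3, {
    blob1 <- matrix(stats::rnorm(8, sd = 0.1), 4, 2)
    blob2 <- matrix(stats::rnorm(8, mean = 10, sd = 0.1), 4, 2)
  })
  X <- rbind(blob1, blob2)
  fit <- kmeans_fit(X, 2, seed = 5, n_restarts = 20)
  grp <- fit$assignments
  expect_equal(length(unique(grp[1:4])), 1)
  expect_equal(length(unique(grp[5:8])), 1)
  expect_false(grp[1] == grp[5])
  expect_equal(fit$sse, brute_force_sse(X, 2), tolerance = 1e-9)
})

test_that("restarted Lloyd attains the exhaustive global minimum on small instances", {
  cases <- list(
    list(n = 6, d = 1, k = 2), list(n = 6, d = 2, k = 3),
    list(n = 7, d = 2, k = 2), list(n = 8, d = 2, k = 3),
    list(n = 8, d = 1, k = 3)
  )
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    withr::with_seed(100 + ci,
      X <- matrix(stats::runif(cs$n * cs$d, 0, 10), cs$n, cs$d))
    fit <- kmeans_fit(X, cs$k, seed = ci, n_restarts = 20)
    expect_equal(fit$sse, brute_force_sse(X, cs$k), tolerance = 1e-6,
                 label = sprintf("case n=%d d=%d k=%d", cs$n, cs$d, cs$k))
  }
})

test_that("SSE is non-increasing across Lloyd iterations", {
  withr::with_seed(4, X <- matrix(stats::rnorm(200), 100, 2))
  fit <- kmeans_fit(X, 4, seed = 9, n_restarts = 3)
  expect_true(all(diff(fit$sse_history) <= 1e-9))
})

test_that("agreement with an independent k-means implementation on separated data", {
  withr::with_seed(6, {
    X <- rbind(matrix(stats::rnorm(60, 0, 0.3), 30, 2),
               matrix(stats::rnorm(60, 8, 0.3), 30, 2),
               matrix(stats::rnorm(60, -8, 0.3), 30, 2))
  })
  ours <- kmeans_fit(X, 3, seed = 2)
  ref <- stats::kmeans(X, 3, nstart = 20)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-6)
})

test_that("elbow scan produces a monotone curve and recovers planted modes", {
  ds <- make_fixture(n_majority = 90, n_minority = 5, n_modes = 3,
                     side = 24, noise_sd = 6, seed = 12)
  fm <- extract_features(ds, make_fallback_extractor(12))
  X <- fm$values[ds$labels == 0, ]
  curve <- elbow_scan(X, cluster_n = 8, seed = 1)
  expect_true(all(diff(curve$sse_values) <= 1e-9))
  expect_equal(curve$chosen_k, 3)
  # restart stability: a different seed picks the same elbow
  expect_equal(elbow_scan(X, cluster_n = 8, seed = 999)$chosen_k, 3)
})

test_that("cluster_n = 1 yields a length-1 curve choosing k = 1", {
  withr::with_seed(8, X <- matrix(stats::rnorm(40), 20, 2))
  curve <- elbow_scan(X, cluster_n = 1, seed = 1)
  expect_equal(length(curve$k_values), 1)
  expect_equal(curve$chosen_k, 1)
})

test_that("chord-distance elbow selection matches hand evaluation", {
  # normalized points (0,1),(1/4,1/9),(1/2,1/18),(3/4,1/45),(1,0):
  # distances from the chord peak at k = 2
  curve <- list(k_values = 1:5, sse_values = c(100, 20, 15, 12, 10))
  expect_equal(select_elbow_k(curve), 2)
  # strictly linear decline: all distances 0, tie -> smallest k
  expect_equal(select_elbow_k(list(k_values = 1:5,
                                   sse_values = c(50, 40, 30, 20, 10))), 1)
  # flat curve -> 1
  expect_equal(select_elbow_k(list(k_values = 1:4,
                                   sse_values = rep(7, 4))), 1)
})

test_that("elbow choice is invariant to affine rescaling of the SSE axis", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      sv <- sort(stats::runif(8, 0, 100), decreasing = TRUE)
      curve <- list(k_values = 1:8, sse_values = sv)
      k0 <- select_elbow_k(curve)
      a <- stats::runif(1, 0.1, 50)
      b <- stats::runif(1, -5, 5)
      expect_equal(select_elbow_k(list(k_values = 1:8,
                                       sse_values = a * sv + b)), k0)
    }
  })
})

test_that("empty-cluster repair keeps k constant on duplicate-heavy data", {
  X <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  fit <- kmeans_fit(X, 3, seed = 1, n_restarts = 5)
  expect_equal(nrow(fit$centers), 3)
  expect_true(all(fit$assignments %in% 1:3))
})
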