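test_that("metrics match hand-evaluated formulas on a worked confusion matrix", {
  cm <- structure(list(tp = 3, tn = 4, fp = 1, fn = 2),
                  class = "confusion_matrix")
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(m$f1, 4), 0.6667)
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(23, {
    for (rep in 1:1000) {
      counts <- stats::rpois(4, lambda = sample(c(1, 5, 40), 1))
      cm <- structure(list(tp = counts[1], tn = counts[2],
                           fp = counts[3], fn = counts[4]),
                      class = "confusion_matrix")
      total <- sum(counts)
      if (total == 0) next
      m <- metrics_from_confusion(cm)
      # independent recomputation straight from the counts
      acc2 <- (cm$tp + cm$tn) / total
      p2 <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
      r2 <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
      f2 <- if (p2 + r2 > 0) 2 * p2 * r2 / (p2 + r2) else 0
      expect_equal(m$accuracy, acc2, tolerance = 1e-12)
      expect_equal(m$precision, p2, tolerance = 1e-12)
      expect_equal(m$recall, r2, tolerance = 1e-12)
      expect_equal(m$f1, f2, tolerance = 1e-12)
      expect_gte(m$f1, min(p2, r2) - 1e-12)
      expect_lte(m$f1, max(p2, r2) + 1e-12)
    }
  })
})

test_that("perfect and degenerate predictors score as expected", {
  y <- c(rep(0L, 18), rep(1L, 2))
  map <- label_map(3)
  perfect <- ifelse(y == 1L, 3L, 0L)
  m1 <- evaluate_binary(y, perfect, map)$metrics
  expect_equal(c(m1$accuracy, m1$precision, m1$recall, m1$f1), rep(1, 4))
  all_major <- rep(0L, 20)
  m0 <- evaluate_binary(y, all_major, map)$metrics
  expect_equal(m0$recall, 0)
  expect_equal(m0$accuracy, 0.9)
  expect_true("precision" %in% m0$zero_division)
  expect_error(evaluate_binary(y, all_major[-1], map), "lengths differ")
})

test_that("scoring is invariant to which majority-cluster label a prediction carries", {
  withr::with_seed(31, {
    map <- label_map(4)
    y <- sample(0:1, 50, replace = TRUE)
    pred <- ifelse(y == 1, 4L, sample(0:3, 50, replace = TRUE))
    pred[1:10] <- sample(0:4, 10, replace = TRUE)  # add some errors
    shuffled <- ifelse(pred < 4, sample(0:3, 50, replace = TRUE), pred)
    m1 <- evaluate_binary(y, pred, map)$metrics
    m2 <- evaluate_binary(y, shuffled, map)$metrics
    expect_equal(m1$accuracy, m2$accuracy)
    expect_equal(m1$f1, m2$f1)
  })
})

test_that("best-epoch selection takes the argmax with the earliest tie winning", {
  expect_equal(best_epoch_index(c(0.8, 0.95, 0.95, 0.90)), 2)
  expect_equal(best_epoch_index(c(0.5)), 1)
})

test_that("the linear classifier separates well-separated synthetic features", {
  ds <- make_fixture(n_majority = 100, n_minority = 10, n_modes = 2,
                     side = 20, noise_sd = 6, seed = 9)
  sp <- stratified_split(ds, split_spec(seed = 9))
  ex <- make_fallback_extractor(10)
  ftr <- extract_features(sp$train, ex)
  part <- partition_majority(sp$train, ftr, cluster_n = 5, seed = 9)
  val <- relabel_with_model(sp$val, extract_features(sp$val, ex),
                            part$model, part$label_map)
  fit <- train_classifier(part$dataset, val, linear_classifier(),
                          train_config(seed = 9), part$label_map, ex)
  expect_equal(fit$best_val_acc, 1.0)
  expect_lte(fit$best_epoch, 50)
  expect_equal(nrow(fit$history), 50)
  # determinism: identical history on a rerun
  fit2 <- train_classifier(part$dataset, val, linear_classifier(),
                           train_config(seed = 9), part$label_map, ex)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
})

test_that("training validates its inputs", {
  ds <- make_fixture(n_majority = 20, n_minority = 4, n_modes = 1,
                     side = 12, noise_sd = 5)
  ex <- make_fallback_extractor(6)
  map <- label_map(1)
  empty <- subset_images(ds, integer(0))
  expect_error(train_classifier(empty, ds, linear_classifier(),
                                train_config(), map, ex), "empty")
  expect_error(train_classifier(ds, ds, linear_classifier(),
                                train_config(class_weights = c(1, 2, 3)),
                                map, ex), "class_weights length")
})

test_that("the experiment suite emits six named rows with the four metrics", {
  ds <- make_fixture(n_majority = 120, n_minority = 10, n_modes = 2,
                     side = 16, noise_sd = 8, seed = 3)
  suite <- run_experiment_suite(ds, extractor = make_fallback_extractor(8),
                                cfg = train_config(epochs = 10),
                                cluster_n = 4, seed = 3)
  df <- as.data.frame(suite)
  expect_equal(df$configuration,
               c("baseline", "weighted-aug", "weighted-clf", "mciic",
                 "mciic+weighted-aug", "mciic+weighted-clf"))
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in% names(df)))
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
  expect_error(run_experiment_suite(ds, configurations = "no-such-row"),
               "unknown configurations")
})

test_that("the experiment suite is reproducible bit-for-bit from its seed", {
  ds <- make_fixture(n_majority = 80, n_minority = 8, n_modes = 2,
                     side = 16, noise_sd = 8, seed = 13)
  args <- list(ds, extractor = make_fallback_extractor(8),
               cfg = train_config(epochs = 6), cluster_n = 3, seed = 13,
               configurations = c("baseline", "mciic+weighted-aug"))
  s1 <- do.call(run_experiment_suite, args)
  s2 <- do.call(run_experiment_suite, args)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
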