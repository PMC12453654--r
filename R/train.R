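# Trainer with the reference hyperparameter schedule (SGD with momentum,
# step-decayed learning rate, optional class-weighted cross-entropy),
# validation-time binary model selection, confusion-matrix construction and
# the derived metrics, plus the six-configuration experiment harness.

#' Training configuration
#'
#' Defaults follow the reference schedule: 50 epochs of stochastic gradient
#' descent with momentum 0.9 and weight decay 5e-4, batch size 256,
#' cross-entropy loss, initial learning rate 0.005 reduced to one tenth
#' after every 12 epochs.
#'
#' @param epochs number of training epochs.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient (bias excluded).
#' @param batch_size minibatch size.
#' @param class_weights optional per-class loss weights (see
#'   [loss_weights_for_training()]); `NULL` for the unweighted loss.
#' @param seed integer seed for shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 50L, lr = 0.005, lr_decay = 0.1,
                         decay_every = 12L, momentum = 0.9,
                         weight_decay = 5e-4, batch_size = 256L,
                         class_weights = NULL, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, lr_decay > 0, decay_every >= 1,
            momentum >= 0, weight_decay >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Lightweight reference classifier
#'
#' A multinomial linear (softmax) model on extracted feature vectors, trained
#' by minibatch SGD under a [train_config()]. It fills the classifier
#' contract — deterministic `predict` after `fit`, label range matching the
#' training label set — at desk scale; a deep fine-tuned backbone satisfies
#' the same contract at full scale but requires an external runtime.
#'
#' @return a `classifier_contract` of type `"linear_softmax"`.
#' @export
linear_classifier <- function() {
  structure(list(type = "linear_softmax"), class = "classifier_contract")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train a classifier with binary validation-accuracy model selection
#'
#' Runs the configured epoch schedule on the training set. After every epoch
#' the validation predictions are folded to binary with the label map and
#' binary accuracy is computed; the returned weights are those of the epoch
#' with the highest binary validation accuracy (earliest epoch on ties).
#' When a [weighted_augment_sampler()] is supplied, each epoch trains on that
#' epoch's stochastically augmented stream (features of replaced images are
#' re-extracted); otherwise features are extracted once.
#'
#' @param ds_train,ds_val training and validation `labeled_image_set`s
#'   sharing one label set.
#' @param clf a [linear_classifier()].
#' @param cfg a [train_config()].
#' @param map the `label_map` used for binary fold-back.
#' @param extractor a `feature_extractor`.
#' @param sampler optional `weighted_augment_sampler` over `ds_train`.
#' @return an `mciic_classifier` with the selected weights, `best_epoch`,
#'   and a `history` data frame (epoch, train_loss, val_acc_binary).
#' @export
train_classifier <- function(ds_train, ds_val, clf, cfg, map, extractor,
                             sampler = NULL) {
  stopifnot(inherits(clf, "classifier_contract"),
            inherits(cfg, "train_config"), inherits(map, "label_map"))
  if (n_images(ds_train) == 0L || n_images(ds_val) == 0L) {
    stop("empty training or validation split")
  }
  if (!identical(ds_train$label_names, ds_val$label_names)) {
    stop("train and validation splits have different label sets")
  }
  n_classes <- length(ds_train$label_names)
  X_base <- extract_features(ds_train, extractor)$values
  X_val <- extract_features(ds_val, extractor)$values
  y <- ds_train$labels
  y_val_bin <- fold_to_binary(ds_val$labels, map)
  n <- nrow(X_base)
  d <- ncol(X_base)
  W <- matrix(0, d + 1L, n_classes)
  V <- matrix(0, d + 1L, n_classes)
  sw_class <- if (is.null(cfg$class_weights)) rep(1, n_classes) else cfg$class_weights
  if (length(sw_class) != n_classes) {
    stop("class_weights length does not match the number of classes")
  }
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc_binary = numeric(0))
  best_W <- W
  best_acc <- -Inf
  best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_decay^((epoch - 1L) %/% cfg$decay_every)
    X <- X_base
    if (!is.null(sampler)) {
      stream <- sampler$epoch(epoch)
      aug_idx <- which(stream$augmented)
      for (i in aug_idx) {
        X[i, ] <- extract_one(extractor, get_pixels(stream$dataset, i))
      }
    }
    perm <- withr::with_seed(cfg$seed + epoch, sample.int(n))
    loss_num <- 0
    loss_den <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bi <- perm[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- cbind(1, X[bi, , drop = FALSE])
      P <- softmax_rows(Xb %*% W)
      sw <- sw_class[y[bi] + 1L]
      eps <- 1e-12
      loss_num <- loss_num -
        sum(sw * log(P[cbind(seq_along(bi), y[bi] + 1L)] + eps))
      loss_den <- loss_den + sum(sw)
      G <- t(Xb) %*% ((P - Y[bi, , drop = FALSE]) * sw) / sum(sw)
      G[-1L, ] <- G[-1L, ] + cfg$weight_decay * W[-1L, ]
      V <- cfg$momentum * V - lr * G
      W <- W + V
    }
    val_pred <- max.col(cbind(1, X_val) %*% W, ties.method = "first") - 1L
    acc <- mean(fold_to_binary(val_pred, map) == y_val_bin)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = loss_num / loss_den,
                                val_acc_binary = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_W <- W
      best_epoch <- epoch
    }
  }
  structure(list(weights = best_W, n_classes = n_classes,
                 best_epoch = best_epoch, best_val_acc = best_acc,
                 history = history, extractor_tag = extractor$name),
            class = "mciic_classifier")
}

#' Predict labels with a fitted classifier
#' @param fit an `mciic_classifier`.
#' @param features a `feature_matrix` or plain matrix of feature rows.
#' @return integer vector of 0-based predicted labels.
#' @export
predict_labels <- function(fit, features) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  max.col(cbind(1, X) %*% fit$weights, ties.method = "first") - 1L
}

#' Select the best epoch from a validation-accuracy history
#'
#' Argmax with the earliest epoch winning ties — the model-selection rule
#' used by [train_classifier()], exposed for testing.
#'
#' @param val_acc numeric vector of per-epoch validation accuracies.
#' @return the 1-based index of the selected epoch.
#' @export
best_epoch_index <- function(val_acc) {
  which.max(val_acc)  # which.max returns the first maximum
}

#' Binary confusion matrix with the minority-positive convention
#' @param y_true,y_pred 0/1 integer vectors (1 = minority/positive).
#' @return a `confusion_matrix` with tp, tn, fp, fn.
#' @export
binary_confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("minority", "majority"),
                              prediction = c("minority", "majority")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Minority is positive: accuracy = (TP+TN)/(TP+TN+FP+FN), precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R). A zero denominator
#' yields 0 with the corresponding `zero_division` flag set.
#'
#' @param cm a `confusion_matrix`.
#' @param configuration optional identifier recorded on the report.
#' @return a `metrics_report`.
#' @export
metrics_from_confusion <- function(cm, configuration = "") {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  flags <- character(0)
  div0 <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      return(0)
    }
    num / den
  }
  acc <- div0(cm$tp + cm$tn, total, "accuracy")
  prec <- div0(cm$tp, cm$tp + cm$fp, "precision")
  rec <- div0(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (prec + rec == 0) {
    flags <- c(flags, "f1")
    0
  } else {
    2 * prec * rec / (prec + rec)
  }
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 configuration = configuration, zero_division = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s accuracy=%.4f precision=%.4f recall=%.4f f1=%.4f\n",
              if (nzchar(x$configuration)) paste0("[", x$configuration, "]") else "",
              x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$zero_division)) {
    cat("  zero-denominator metrics reported as 0:",
        paste(x$zero_division, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fold multiclass predictions to binary and score them
#'
#' @param y_true_binary 0/1 truth (1 = minority).
#' @param y_pred_multiclass integer predictions in `[0, Nc]`.
#' @param map the `label_map`.
#' @param configuration optional identifier for the report.
#' @return list with `confusion` (a `confusion_matrix`) and `metrics`
#'   (a `metrics_report`).
#' @export
evaluate_binary <- function(y_true_binary, y_pred_multiclass, map,
                            configuration = "") {
  if (length(y_true_binary) != length(y_pred_multiclass)) {
    stop("truth and prediction lengths differ")
  }
  pred_bin <- fold_to_binary(y_pred_multiclass, map)
  cm <- binary_confusion(as.integer(y_true_binary), pred_bin)
  list(confusion = cm, metrics = metrics_from_confusion(cm, configuration))
}

#' Heatmap plot of a binary confusion matrix
#' @param cm a `confusion_matrix`.
#' @param path output PNG path.
#' @param title plot title.
#' @return invisibly, `path`.
#' @export
plot_confusion <- function(cm, path, title = "Confusion matrix") {
  m <- matrix(c(cm$tn, cm$fn, cm$fp, cm$tp), 2, 2)
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(1:2, 1:2, m, col = grDevices::hcl.colors(64, "Blues 3",
                                                           rev = TRUE),
                  xlab = "prediction", ylab = "truth", axes = FALSE,
                  main = title)
  graphics::axis(1, at = 1:2, labels = c("majority", "minority"))
  graphics::axis(2, at = 1:2, labels = c("majority", "minority"))
  for (i in 1:2) for (j in 1:2) {
    graphics::text(i, j, m[i, j], cex = 1.5)
  }
  invisible(path)
}

suite_config_names <- function() {
  c("baseline", "weighted-aug", "weighted-clf",
    "mciic", "mciic+weighted-aug", "mciic+weighted-clf")
}

#' Run the six-configuration comparison experiment
#'
#' On one shared stratified split, trains and scores the six configurations:
#' the plain binary baseline, binary with class-weighted augmentation, binary
#' with the class-weighted loss, majority clustering alone, and majority
#' clustering combined with each weighting scheme. All configurations share
#' the same extractor, seed and training schedule; weights for the combined
#' rows are computed on the post-relabeling multiclass counts.
#'
#' @param ds a binary imbalanced `labeled_image_set`.
#' @param extractor a `feature_extractor`.
#' @param cfg a [train_config()] (class weights are filled per row).
#' @param spec a [split_spec()].
#' @param cluster_n maximum cluster count for the elbow scan.
#' @param aug an [augment_spec()].
#' @param seed integer seed shared across rows.
#' @param configurations subset of configuration names to run (default all 6).
#' @return an `experiment_suite`: a data frame of per-configuration metrics
#'   (accuracy, minority precision/recall/F1, chosen Nc) with the per-row
#'   details (confusion matrices, histories, elbow curve) in attributes.
#' @export
run_experiment_suite <- function(ds, extractor = make_fallback_extractor(16L),
                                 cfg = train_config(), spec = split_spec(),
                                 cluster_n = 8L, aug = augment_spec(),
                                 seed = 1L,
                                 configurations = suite_config_names()) {
  stopifnot(length(ds$label_names) == 2L)
  unknown <- setdiff(configurations, suite_config_names())
  if (length(unknown)) stop("unknown configurations: ",
                            paste(unknown, collapse = ", "))
  spec$seed <- as.integer(seed)
  splits <- stratified_split(ds, spec)
  feat <- lapply(splits, extract_features, ex = extractor)
  min_lab <- minority_label(ds)
  y_test_bin <- as.integer(splits$test$labels == min_lab)

  # binary relabeling (majority -> 0, minority -> 1) via a forced Nc = 1
  bin_train <- partition_majority(splits$train, feat$train, seed = seed, nc = 1L)
  bin_sets <- list(
    train = bin_train$dataset,
    val = relabel_with_model(splits$val, feat$val, bin_train$model,
                             bin_train$label_map),
    test = relabel_with_model(splits$test, feat$test, bin_train$model,
                              bin_train$label_map)
  )

  # majority clustering with elbow-selected Nc on the training majority only
  mc_train <- partition_majority(splits$train, feat$train,
                                 cluster_n = cluster_n, seed = seed)
  mc_sets <- list(
    train = mc_train$dataset,
    val = relabel_with_model(splits$val, feat$val, mc_train$model,
                             mc_train$label_map),
    test = relabel_with_model(splits$test, feat$test, mc_train$model,
                              mc_train$label_map)
  )

  run_row <- function(name) {
    use_mciic <- grepl("^mciic", name)
    sets <- if (use_mciic) mc_sets else bin_sets
    map <- if (use_mciic) mc_train$label_map else bin_train$label_map
    tab <- class_weights(label_counts(sets$train))
    row_cfg <- cfg
    row_cfg$seed <- as.integer(seed)
    sampler <- NULL
    if (grepl("weighted-aug", name)) {
      sampler <- weighted_augment_sampler(sets$train, tab, aug, seed = seed)
    }
    if (grepl("weighted-clf", name)) {
      row_cfg$class_weights <- loss_weights_for_training(tab)
    }
    fit <- train_classifier(sets$train, sets$val, linear_classifier(),
                            row_cfg, map, extractor, sampler = sampler)
    pred <- predict_labels(fit, feat$test)
    ev <- evaluate_binary(y_test_bin, pred, map, configuration = name)
    list(name = name, fit = fit, eval = ev,
         nc = map$n_majority_clusters)
  }

  rows <- lapply(configurations, run_row)
  report <- do.call(rbind, lapply(rows, function(r) {
    data.frame(configuration = r$name,
               accuracy = r$eval$metrics$accuracy,
               precision = r$eval$metrics$precision,
               recall = r$eval$metrics$recall,
               f1 = r$eval$metrics$f1,
               nc = r$nc)
  }))
  structure(report,
            details = rows,
            elbow = mc_train$elbow,
            class = c("experiment_suite", "data.frame"))
}
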