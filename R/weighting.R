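# Class-weight computation shared by the weighted loss and the weighted
# augmentation sampler, plus the three stochastic augmentation operators
# (brightness, rotation, horizontal flip).

#' Per-class weights and augmentation probabilities
#'
#' Implements `w_i = total_samples / (n_i * n_classes)`. The identity
#' `sum_i n_i * w_i = total_samples` holds exactly. Augmentation
#' probabilities are the weights normalized by their maximum, which reduces
#' to `p_i = n_min / n_i`: the rarest class is always augmented (p = 1) and
#' larger classes proportionally less — counts (10, 20, 30) give
#' probabilities (1, 0.5, 0.33).
#'
#' @param counts vector of positive per-class sample counts.
#' @return a `class_weight_table` with `counts`, `weights`, `probabilities`.
#' @export
class_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(counts < 1)) {
    stop("all class counts must be >= 1")
  }
  total <- sum(counts)
  w <- total / (counts * length(counts))
  p <- w / max(w)
  structure(list(counts = counts, weights = w, probabilities = p),
            class = "class_weight_table")
}

#' @export
print.class_weight_table <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.class_weight_table <- function(x, ...) {
  data.frame(class = seq_along(x$counts) - 1L, count = x$counts,
             weight = x$weights, probability = x$probabilities)
}

#' Per-class multipliers for the weighted cross-entropy loss
#'
#' Returns the table's weights unchanged — the same formula drives both the
#' weighted loss and the augmentation probabilities; the loss uses the raw
#' weights so that minority misclassification carries a proportionally higher
#' penalty.
#'
#' @param table a `class_weight_table`.
#' @return numeric vector of per-class loss weights.
#' @export
loss_weights_for_training <- function(table) {
  stopifnot(inherits(table, "class_weight_table"))
  table$weights
}

#' Specification of the stochastic augmentation operators
#'
#' @param brightness length-2 range of multiplicative brightness factors.
#' @param rotation length-2 range of rotation angles in degrees.
#' @param flip_prob probability of a horizontal flip.
#' @return an `augment_spec`.
#' @export
augment_spec <- function(brightness = c(0.75, 1.25), rotation = c(-10, 10),
                         flip_prob = 0.5) {
  stopifnot(length(brightness) == 2L, length(rotation) == 2L,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(brightness = brightness, rotation = rotation,
                 flip_prob = flip_prob),
            class = "augment_spec")
}

#' Apply one random augmentation draw to an image
#'
#' In order: multiplicative brightness scaling (uniform in the spec's range,
#' clipped to the 0--255 pixel range), rotation about the centre (uniform
#' angle, bilinear interpolation, edges filled with the nearest border
#' value), then a horizontal flip with the spec's probability. Output shape
#' equals input shape; draws come from the current RNG state, so seed the
#' caller for determinism.
#'
#' @param px an `H x W` matrix or `H x W x C` array on the 0--255 scale.
#' @param spec an [augment_spec()].
#' @return augmented pixels, same shape and scale.
#' @export
augment_image <- function(px, spec = augment_spec()) {
  b <- stats::runif(1, spec$brightness[1], spec$brightness[2])
  out <- clip_pixels(px * b)
  ang <- stats::runif(1, spec$rotation[1], spec$rotation[2])
  if (ang != 0) out <- apply_per_channel(out, function(m) rotate_channel(m, ang))
  if (stats::runif(1) < spec$flip_prob) {
    out <- apply_per_channel(out, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
  }
  clip_pixels(out)
}

#' Class-weighted augmentation sampler
#'
#' For each epoch, every training image of class `i` is replaced by an
#' augmented copy with probability `p_i` (the class-weight table's normalized
#' probability); the rarest class (p = 1) is always augmented. Replacement
#' keeps the epoch size fixed. The stream is deterministic given `seed`: each
#' epoch draws from seed `seed + epoch`.
#'
#' @param ds a `labeled_image_set` (pixels or paths available).
#' @param table a `class_weight_table` over the dataset's classes.
#' @param spec an [augment_spec()].
#' @param seed integer base seed.
#' @return a `weighted_augment_sampler` whose `$epoch(e)` returns a list with
#'   `dataset` (the epoch's image set) and `augmented` (logical mask of
#'   replaced samples).
#' @export
weighted_augment_sampler <- function(ds, table, spec = augment_spec(),
                                     seed = 1L) {
  stopifnot(inherits(ds, "labeled_image_set"),
            inherits(table, "class_weight_table"))
  if (length(table$probabilities) != length(ds$label_names)) {
    stop("weight table does not cover the dataset's classes")
  }
  p <- table$probabilities
  seed <- as.integer(seed)
  epoch_fn <- function(epoch) {
    withr::with_seed(seed + as.integer(epoch), {
      n <- n_images(ds)
      aug <- stats::runif(n) < p[ds$labels + 1L]
      pixels <- vector("list", n)
      for (i in which(aug)) {
        pixels[[i]] <- augment_image(get_pixels(ds, i), spec)
      }
      epoch_ds <- ds
      if (is.null(epoch_ds$pixels)) epoch_ds$pixels <- vector("list", n)
      epoch_ds$pixels[aug] <- pixels[aug]
      list(dataset = epoch_ds, augmented = aug)
    })
  }
  structure(list(epoch = epoch_fn, probabilities = p, spec = spec,
                 seed = seed),
            class = "weighted_augment_sampler")
}

#' Export a class-weight table as CSV
#' @param table a `class_weight_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_weight_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
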