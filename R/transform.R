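# Core relabeling: partition the majority class of a binary set into Nc
# k-means clusters, emit an (Nc+1)-class dataset plus a label map, and fold
# multiclass predictions back to binary.

#' Construct a label map for majority-cluster relabeling
#'
#' Records the correspondence between the original binary labels and the
#' expanded multiclass labels: majority clusters take labels `0..Nc-1` and
#' the minority class takes label `Nc`.
#'
#' @param n_majority_clusters `Nc`, a positive integer.
#' @param original_majority_name,original_minority_name original class names.
#' @return an object of class `label_map`.
#' @export
label_map <- function(n_majority_clusters, original_majority_name = "majority",
                      original_minority_name = "minority") {
  nc <- as.integer(n_majority_clusters)
  if (nc < 1L) stop("Nc must be >= 1")
  structure(
    list(n_majority_clusters = nc,
         majority_labels = 0:(nc - 1L),
         minority_label = nc,
         original_majority_name = original_majority_name,
         original_minority_name = original_minority_name),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d majority clusters (labels 0..%d), minority = %d\n",
              x$n_majority_clusters, x$n_majority_clusters - 1L,
              x$minority_label))
  cat(sprintf("  majority '%s', minority '%s'\n",
              x$original_majority_name, x$original_minority_name))
  invisible(x)
}

#' Partition the majority class into clusters and relabel
#'
#' The majority samples of a binary imbalanced set are clustered by k-means
#' on their feature vectors; the number of clusters `Nc` is selected with the
#' elbow criterion over `1..cluster_n` (or forced with `nc`). Each majority
#' sample is relabeled by its cluster index `0..Nc-1` and every minority
#' sample receives label `Nc`, turning the binary problem into an
#' `(Nc+1)`-class problem. No sample is discarded: the under-sampling effect
#' is the reduction of the per-label count as the majority splits into `Nc`
#' classes.
#'
#' @param ds a binary `labeled_image_set` with a strict majority.
#' @param features a `feature_matrix` aligned with `ds` rows.
#' @param cluster_n maximum cluster count scanned by the elbow method.
#' @param seed integer seed.
#' @param nc optionally force `Nc` and skip the elbow scan.
#' @return a list with `dataset` (the relabeled `labeled_image_set`),
#'   `label_map`, `elbow` (the `elbow_curve`, or `NULL` when `nc` is forced),
#'   and `model` (the winning `cluster_model`).
#' @export
partition_majority <- function(ds, features, cluster_n = 10L, seed = 1L,
                               nc = NULL) {
  stopifnot(inherits(ds, "labeled_image_set"),
            inherits(features, "feature_matrix"))
  if (length(ds$label_names) != 2L) {
    stop("majority clustering requires a binary dataset; got ",
         length(ds$label_names), " classes")
  }
  if (!identical(features$ids, ds$ids)) {
    stop("feature matrix is not aligned with the dataset")
  }
  min_lab <- minority_label(ds)  # errors on an exactly balanced set
  maj_lab <- 1L - min_lab
  maj_idx <- which(ds$labels == maj_lab)
  X <- features$values[maj_idx, , drop = FALSE]
  if (is.null(nc)) {
    curve <- elbow_scan(X, cluster_n = cluster_n, seed = seed)
    nc <- curve$chosen_k
    model <- curve$models[[nc]]
  } else {
    nc <- as.integer(nc)
    curve <- NULL
    model <- kmeans_fit(X, nc, seed = seed)
  }
  small <- which(tabulate(model$assignments, nbins = nc) <
                   max(2, 0.005 * length(maj_idx)))
  if (length(small) > 0L) {
    warning("majority clusters with very few samples kept: ",
            paste(small - 1L, collapse = ", "))
  }
  new_labels <- ds$labels
  new_labels[maj_idx] <- model$assignments - 1L
  new_labels[ds$labels == min_lab] <- nc
  map <- label_map(nc,
                   original_majority_name = ds$label_names[maj_lab + 1L],
                   original_minority_name = ds$label_names[min_lab + 1L])
  out <- labeled_image_set(
    ids = ds$ids, labels = new_labels,
    label_names = c(paste0("cluster_", 0:(nc - 1L)),
                    ds$label_names[min_lab + 1L]),
    paths = ds$paths, pixels = ds$pixels,
    provenance = paste0(ds$provenance, " | majority split into ", nc,
                        " clusters"),
    mode_labels = ds$mode_labels
  )
  list(dataset = out, label_map = map, elbow = curve, model = model)
}

#' Relabel a held-out binary set with a fitted majority clustering
#'
#' Majority samples are assigned to the nearest fitted cluster centre;
#' minority samples take label `Nc`. Used to carry the training-split
#' clustering onto validation and test splits without refitting.
#'
#' @param ds a binary `labeled_image_set` sharing the original label
#'   vocabulary.
#' @param features a `feature_matrix` aligned with `ds`.
#' @param model the `cluster_model` fitted on the training majority.
#' @param map the corresponding `label_map`.
#' @return the relabeled `labeled_image_set`.
#' @export
relabel_with_model <- function(ds, features, model, map) {
  stopifnot(inherits(map, "label_map"))
  if (!identical(features$ids, ds$ids)) {
    stop("feature matrix is not aligned with the dataset")
  }
  min_name <- map$original_minority_name
  min_lab <- match(min_name, ds$label_names) - 1L
  if (is.na(min_lab)) stop("dataset lacks class '", min_name, "'")
  nc <- map$n_majority_clusters
  new_labels <- integer(n_images(ds))
  maj_idx <- which(ds$labels != min_lab)
  if (length(maj_idx) > 0L) {
    new_labels[maj_idx] <-
      assign_clusters(model, features$values[maj_idx, , drop = FALSE]) - 1L
  }
  new_labels[ds$labels == min_lab] <- nc
  labeled_image_set(
    ids = ds$ids, labels = new_labels,
    label_names = c(paste0("cluster_", 0:(nc - 1L)), min_name),
    paths = ds$paths, pixels = ds$pixels,
    provenance = ds$provenance, mode_labels = ds$mode_labels
  )
}

#' Fold multiclass predictions back to binary
#'
#' Labels below `Nc` (the majority clusters) map to 0 (negative, majority);
#' label `Nc` maps to 1 (positive, minority).
#'
#' @param pred_labels integer labels in `[0, Nc]`.
#' @param map a `label_map`.
#' @return integer vector of 0/1 binary labels (1 = minority/positive).
#' @export
fold_to_binary <- function(pred_labels, map) {
  stopifnot(inherits(map, "label_map"))
  pred_labels <- as.integer(pred_labels)
  nc <- map$n_majority_clusters
  if (any(pred_labels < 0L | pred_labels > nc)) {
    stop("prediction labels out of range [0, ", nc, "]")
  }
  as.integer(pred_labels == nc)
}

#' Imbalance ratio of a binary dataset
#'
#' `100 * minority / majority`, rounded half-up to one decimal place — the
#' convention under which (158442, 3637) prints 2.3, (7430, 1510) prints
#' 20.3 and (11352, 681) prints 6.
#'
#' @param majority_count,minority_count positive integer class sizes with
#'   `majority_count >= minority_count`.
#' @return the ratio as a percentage with one decimal.
#' @export
imbalance_ratio <- function(majority_count, minority_count) {
  if (majority_count < 1 || minority_count < 1) stop("counts must be >= 1")
  if (minority_count > majority_count) {
    stop("minority count exceeds majority count; swap the arguments")
  }
  round_half_up(100 * minority_count / majority_count, 1)
}

#' Serialize a label map to JSON
#' @param map a `label_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_label_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path JSON path.
#' @return a `label_map`.
#' @export
read_label_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  label_map(x$n_majority_clusters, x$original_majority_name,
            x$original_minority_name)
}
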