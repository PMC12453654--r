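#' Construct a labeled image set
#'
#' The pipeline's currency before and after relabeling: an ordered collection
#' of images, each with a unique id and a small non-negative integer label
#' indexing into `label_names`. Pixels may be held in memory (a list of
#' `H x W` matrices or `H x W x C` arrays on the 0--255 scale) or referenced
#' lazily by file path and decoded on first use.
#'
#' @param ids character vector of unique image identifiers.
#' @param labels integer vector of 0-based labels, one per image.
#' @param label_names character vector naming each label value; label `i`
#'   corresponds to `label_names[i + 1]`.
#' @param paths optional character vector of image file paths (lazy pixels).
#' @param pixels optional list of pixel arrays, aligned with `ids`.
#' @param provenance free-text note on where the set came from.
#' @param mode_labels optional integer vector of planted ground-truth mode
#'   indices (used by the synthetic generator; `NA` for minority images).
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(ids, labels, label_names, paths = NULL,
                              pixels = NULL, provenance = "",
                              mode_labels = NULL) {
  ids <- as.character(ids)
  labels <- as.integer(labels)
  if (anyDuplicated(ids)) stop("image ids must be unique")
  if (length(labels) != length(ids)) stop("ids and labels lengths differ")
  if (length(label_names) < 1L) stop("label_names must be non-empty")
  if (any(labels < 0L | labels >= length(label_names))) {
    stop("labels must lie in [0, ", length(label_names), ")")
  }
  if (!is.null(paths) && length(paths) != length(ids)) {
    stop("paths and ids lengths differ")
  }
  if (!is.null(pixels) && length(pixels) != length(ids)) {
    stop("pixels and ids lengths differ")
  }
  structure(
    list(ids = ids, labels = labels, label_names = as.character(label_names),
         paths = paths, pixels = pixels, provenance = provenance,
         mode_labels = mode_labels),
    class = "labeled_image_set"
  )
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cnt <- label_counts(x)
  cat(sprintf("labeled_image_set: %d images, %d classes\n",
              length(x$ids), length(x$label_names)))
  for (i in seq_along(x$label_names)) {
    cat(sprintf("  [%d] %-12s %d\n", i - 1L, x$label_names[i], cnt[i]))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of images in a labeled image set
#' @param ds a `labeled_image_set`.
#' @return integer count.
#' @export
n_images <- function(ds) length(ds$ids)

#' Per-class sample counts
#' @param ds a `labeled_image_set`.
#' @return named integer vector, one entry per label name, in label order.
#' @export
label_counts <- function(ds) {
  cnt <- tabulate(ds$labels + 1L, nbins = length(ds$label_names))
  names(cnt) <- ds$label_names
  cnt
}

#' Identify the minority label of a binary set
#'
#' The minority class is the label with the fewer samples, irrespective of its
#' name. An exactly balanced binary set has no minority and raises an error.
#'
#' @param ds a binary `labeled_image_set`.
#' @return 0-based integer label of the minority class.
#' @export
minority_label <- function(ds) {
  if (length(ds$label_names) != 2L) stop("minority_label() requires a binary set")
  cnt <- label_counts(ds)
  if (cnt[1] == cnt[2]) {
    stop("classes are exactly balanced; there is no minority class ",
         "(majority clustering is not applicable)")
  }
  as.integer(which.min(cnt) - 1L)
}

#' Retrieve decoded pixels for one image
#'
#' Decodes from the stored path when pixels are held lazily; decode failures
#' surface here, at first use, naming the image id.
#'
#' @param ds a `labeled_image_set`.
#' @param i image index (1-based position in the set).
#' @return an `H x W` matrix or `H x W x C` array on the 0--255 scale.
#' @export
get_pixels <- function(ds, i) {
  if (!is.null(ds$pixels) && !is.null(ds$pixels[[i]])) return(ds$pixels[[i]])
  if (is.null(ds$paths) || is.na(ds$paths[i])) {
    stop("no pixels or path stored for image '", ds$ids[i], "'")
  }
  px <- tryCatch(decode_image(ds$paths[i]),
                 error = function(e) {
                   stop("failed to decode image '", ds$ids[i], "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  px
}

#' Subset a labeled image set by position
#' @param ds a `labeled_image_set`.
#' @param idx integer positions to keep.
#' @return a `labeled_image_set` with the selected images, order preserved.
#' @export
subset_images <- function(ds, idx) {
  labeled_image_set(
    ids = ds$ids[idx], labels = ds$labels[idx], label_names = ds$label_names,
    paths = if (is.null(ds$paths)) NULL else ds$paths[idx],
    pixels = if (is.null(ds$pixels)) NULL else ds$pixels[idx],
    provenance = ds$provenance,
    mode_labels = if (is.null(ds$mode_labels)) NULL else ds$mode_labels[idx]
  )
}

# Decode a PNG or JPEG file to pixels on the 0--255 scale. PNG is read with
# the png package; JPEG requires EBImage.
decode_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    px <- px * 255
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package")
    }
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img) * 255
    # EBImage stores (x, y[, c]); transpose to (row, col[, c])
    px <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  px
}

#' Load a labeled image set from an image-folder layout
#'
#' Expects `root/<class_name>/<image files>` with one subdirectory per class.
#' Label names are the subdirectory names in lexicographic order; item order
#' is deterministic (sorted by path). Files that fail to decode are skipped
#' with a warning; a class whose every file fails is an error.
#'
#' @param root path to the dataset root directory.
#' @return a `labeled_image_set` holding file paths (pixels decode lazily).
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) < 2L) stop("expected >= 2 class subdirectories under ", root)
  ids <- character(0)
  labels <- integer(0)
  paths <- character(0)
  label_names <- basename(dirs)
  for (li in seq_along(dirs)) {
    files <- sort(list.files(dirs[li], pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      stop("class directory '", label_names[li], "' contains no images")
    }
    ok <- vapply(files, function(f) {
      tryCatch({ decode_image(f); TRUE },
               error = function(e) {
                 warning("skipping undecodable file ", f, ": ",
                         conditionMessage(e), call. = FALSE)
                 FALSE
               })
    }, logical(1))
    files <- files[ok]
    if (length(files) == 0L) {
      stop("class '", label_names[li], "' has no decodable images")
    }
    ids <- c(ids, file.path(label_names[li], basename(files)))
    labels <- c(labels, rep(li - 1L, length(files)))
    paths <- c(paths, files)
  }
  labeled_image_set(ids, labels, label_names, paths = paths,
                    provenance = paste0("image folder: ", root))
}

#' Specify a train/validation/test split
#'
#' @param train,val,test fractions in (0, 1) summing to 1; the default is the
#'   80-10-10 split used throughout the pipeline.
#' @param seed integer seed controlling the shuffle.
#' @param stratified split within each class (default) or over the pooled set.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1, seed = 1L,
                       stratified = TRUE) {
  fr <- c(train = train, val = val, test = test)
  if (any(fr <= 0) || any(fr >= 1)) stop("split fractions must lie in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to frac;
# ties and leftovers favour earlier parts (train first).
apportion <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_part <- raw - base
    # order by remainder desc, ties by position (train, val, test)
    ord <- order(-frac_part, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Shuffles each class with the spec's seed and apportions it to the three
#' splits by largest remainder, so per-class counts match the fractions to
#' within rounding and the three splits partition the input exactly.
#'
#' @param ds a `labeled_image_set`.
#' @param spec a [split_spec()].
#' @return a list with elements `train`, `val`, `test`, each a
#'   `labeled_image_set`.
#' @export
stratified_split <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "labeled_image_set"), inherits(spec, "split_spec"))
  frac <- c(spec$train, spec$val, spec$test)
  idx_tr <- integer(0); idx_va <- integer(0); idx_te <- integer(0)
  groups <- if (spec$stratified) {
    split(seq_along(ds$labels), ds$labels)
  } else {
    list(all = seq_along(ds$labels))
  }
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (spec$stratified && length(idx) < 3L) {
      stop("class '", ds$label_names[as.integer(g) + 1L],
           "' has fewer samples (", length(idx),
           ") than split parts (3)")
    }
    perm <- withr::with_seed(spec$seed, sample(idx))
    cnt <- apportion(length(idx), frac)
    idx_tr <- c(idx_tr, perm[seq_len(cnt[1])])
    idx_va <- c(idx_va, perm[cnt[1] + seq_len(cnt[2])])
    idx_te <- c(idx_te, perm[cnt[1] + cnt[2] + seq_len(cnt[3])])
  }
  list(train = subset_images(ds, sort(idx_tr)),
       val = subset_images(ds, sort(idx_va)),
       test = subset_images(ds, sort(idx_te)))
}
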