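#' Deterministic fallback feature extractor
#'
#' Resizes each image to `side x side` grayscale with bilinear interpolation,
#' flattens it, and standardizes the vector per image (zero mean, unit
#' population variance). Zero-variance (constant) images standardize to the
#' zero vector. The extractor is a pure function of the pixels, so repeated
#' extraction is bit-identical — the property clustering and the tests rely
#' on. Output dimension is `side^2`.
#'
#' @param side target side length in pixels; must be >= 2.
#' @return a `feature_extractor` object.
#' @export
make_fallback_extractor <- function(side = 16L) {
  side <- as.integer(side)
  if (side < 2L) stop("side must be >= 2")
  structure(
    list(name = paste0("fallback:", side), output_dim = side^2L, side = side),
    class = c("fallback_extractor", "feature_extractor")
  )
}

#' Resolve a backbone identifier to a feature extractor
#'
#' Accepts `"fallback:<side>"` for the deterministic fallback extractor.
#' The `"deep18"` token names the 18-layer residual-network contract (512
#' features from the penultimate layer of an ImageNet-pretrained network);
#' no inference runtime for it ships with this package, so requesting it
#' raises an informative error directing users to the fallback extractor.
#'
#' @param backbone a string, e.g. `"fallback:16"`.
#' @return a `feature_extractor`.
#' @export
make_backbone <- function(backbone = "fallback:16") {
  if (identical(backbone, "deep18")) {
    stop("the 'deep18' backbone (512-feature pretrained residual network) ",
         "requires an external deep-learning runtime and pretrained weights, ",
         "neither of which ships with this package; use 'fallback:<side>'")
  }
  if (grepl("^fallback:[0-9]+$", backbone)) {
    side <- as.integer(sub("^fallback:", "", backbone))
    return(make_fallback_extractor(side))
  }
  stop("unknown backbone identifier: '", backbone, "'")
}

#' Apply a feature extractor to one image
#'
#' Generic of the extractor contract: implementations must be pure,
#' deterministic functions of the pixels returning a length-`output_dim`
#' numeric vector.
#'
#' @param ex a `feature_extractor`.
#' @param px pixel matrix or array on the 0--255 scale.
#' @return numeric feature vector of length `ex$output_dim`.
#' @export
extract_one <- function(ex, px) UseMethod("extract_one")

#' @export
extract_one.fallback_extractor <- function(ex, px) {
  g <- to_gray(px)
  r <- resize_bilinear(g, ex$side, ex$side)
  v <- as.vector(r)
  mu <- mean(v)
  va <- mean((v - mu)^2)
  # constant image -> zero vector; tolerance absorbs resampling float dust
  if (va < 1e-12) return(rep(0, length(v)))
  (v - mu) / sqrt(va)
}

#' Extract features for every image in a set
#'
#' Applies the extractor to each image in order; row `i` of the result is the
#' feature vector of image `i`. Grayscale images fed to a 3-channel contract
#' are channel-replicated internally by the grayscale conversion.
#'
#' @param ds a `labeled_image_set`.
#' @param ex a `feature_extractor`, e.g. from [make_fallback_extractor()].
#' @return a `feature_matrix`: list with `values` (an `n x d` matrix with ids
#'   as rownames), `ids`, and `extractor_tag`.
#' @export
extract_features <- function(ds, ex) {
  stopifnot(inherits(ds, "labeled_image_set"), inherits(ex, "feature_extractor"))
  n <- n_images(ds)
  vals <- matrix(0, n, ex$output_dim)
  for (i in seq_len(n)) {
    v <- extract_one(ex, get_pixels(ds, i))
    if (length(v) != ex$output_dim) {
      stop("extractor returned ", length(v), " features for image '",
           ds$ids[i], "', expected ", ex$output_dim)
    }
    vals[i, ] <- v
  }
  if (any(!is.finite(vals))) stop("feature matrix contains non-finite entries")
  rownames(vals) <- ds$ids
  structure(list(values = vals, ids = ds$ids, extractor_tag = ex$name),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d x %d (%s)\n",
              nrow(x$values), ncol(x$values), x$extractor_tag))
  invisible(x)
}

#' Save a feature matrix as a text file pair
#'
#' Writes ids one per line to `<prefix>.ids.txt` and the matrix
#' whitespace-delimited to `<prefix>.mat.txt`.
#'
#' @param fm a `feature_matrix`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
save_feature_matrix <- function(fm, prefix) {
  ids_path <- paste0(prefix, ".ids.txt")
  mat_path <- paste0(prefix, ".mat.txt")
  writeLines(fm$ids, ids_path)
  utils::write.table(fm$values, mat_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(ids = ids_path, matrix = mat_path))
}

#' Load a feature matrix saved by [save_feature_matrix()]
#' @param prefix path prefix used when saving.
#' @param extractor_tag tag to record on the loaded matrix.
#' @return a `feature_matrix`.
#' @export
load_feature_matrix <- function(prefix, extractor_tag = "loaded") {
  ids <- readLines(paste0(prefix, ".ids.txt"))
  vals <- as.matrix(utils::read.table(paste0(prefix, ".mat.txt")))
  dimnames(vals) <- list(ids, NULL)
  if (nrow(vals) != length(ids)) stop("ids and matrix row counts differ")
  structure(list(values = vals, ids = ids, extractor_tag = extractor_tag),
            class = "feature_matrix")
}
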