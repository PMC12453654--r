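# Synthetic imbalanced image sets with planted majority-mode structure.
# Majority images are drawn round-robin from n_modes parametric patterns
# (Gaussian blobs at mode-specific offsets); minority images use a distinct
# ring pattern. Additive Gaussian pixel noise is the single separability
# knob, so every pipeline stage is testable without external downloads.

#' Specification of a synthetic imbalanced image set
#'
#' @param n_majority,n_minority class sizes; `n_majority > n_minority >= 1`.
#' @param n_modes number of planted visual modes in the majority class.
#' @param side image side length in pixels (>= 8).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise on
#'   the 0--255 scale.
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_majority = 200L, n_minority = 12L, n_modes = 3L,
                           side = 32L, noise_sd = 8, seed = 1L) {
  n_majority <- as.integer(n_majority)
  n_minority <- as.integer(n_minority)
  n_modes <- as.integer(n_modes)
  side <- as.integer(side)
  if (!(n_majority > n_minority && n_minority >= 1L)) {
    stop("need n_majority > n_minority >= 1")
  }
  if (n_modes < 1L) stop("n_modes must be >= 1")
  if (side < 8L) stop("image side too small to render patterns (need >= 8)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_majority = n_majority, n_minority = n_minority,
                 n_modes = n_modes, side = side, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

render_blob <- function(side, angle, amplitude = 190, background = 25) {
  ctr <- (side + 1) / 2
  r0 <- side / 4
  cy <- ctr + r0 * sin(angle)
  cx <- ctr + r0 * cos(angle)
  sg <- side / 8
  rr <- matrix(rep(seq_len(side), times = side), side, side)
  cc <- matrix(rep(seq_len(side), each = side), side, side)
  background + amplitude * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * sg^2))
}

render_ring <- function(side, amplitude = 190, background = 25) {
  ctr <- (side + 1) / 2
  rr <- matrix(rep(seq_len(side), times = side), side, side)
  cc <- matrix(rep(seq_len(side), each = side), side, side)
  d <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  background + amplitude * exp(-((d - side / 3)^2) / (2 * (side / 12)^2))
}

#' Generate a synthetic imbalanced image set
#'
#' Majority images cycle round-robin through `n_modes` blob patterns placed
#' at distinct angular offsets; minority images use a ring pattern maximally
#' distinct from every blob, so minority-versus-majority difficulty is
#' governed only by the imbalance. Gaussian noise is added per pixel and the
#' result is rounded and clipped to the 0--255 integer range. The planted
#' mode index of each majority image is recorded in `mode_labels` (`NA` for
#' minority images). Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a `labeled_image_set` with in-memory pixels; label 0 is the
#'   majority class ("majority"), label 1 the minority ("minority").
#' @export
generate_imbalanced_images <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  side <- spec$side
  templates <- lapply(seq_len(spec$n_modes) - 1L, function(m) {
    render_blob(side, 2 * pi * m / spec$n_modes)
  })
  ring <- render_ring(side)
  n <- spec$n_majority + spec$n_minority
  pixels <- vector("list", n)
  modes <- rep(NA_integer_, n)
  withr::with_seed(spec$seed, {
    for (i in seq_len(spec$n_majority)) {
      m <- ((i - 1L) %% spec$n_modes) + 1L
      modes[i] <- m
      img <- templates[[m]] +
        if (spec$noise_sd > 0) stats::rnorm(side^2, sd = spec$noise_sd) else 0
      pixels[[i]] <- clip_pixels(round(img))
    }
    for (j in seq_len(spec$n_minority)) {
      img <- ring +
        if (spec$noise_sd > 0) stats::rnorm(side^2, sd = spec$noise_sd) else 0
      pixels[[spec$n_majority + j]] <- clip_pixels(round(img))
    }
  })
  ids <- c(sprintf("majority_%04d", seq_len(spec$n_majority)),
           sprintf("minority_%04d", seq_len(spec$n_minority)))
  labels <- c(rep(0L, spec$n_majority), rep(1L, spec$n_minority))
  labeled_image_set(ids, labels, c("majority", "minority"), pixels = pixels,
                    provenance = sprintf(
                      "synthetic: %d modes, noise sd %.3g, seed %d",
                      spec$n_modes, spec$noise_sd, spec$seed),
                    mode_labels = modes)
}

#' Write a labeled image set to an image-folder layout
#'
#' Creates one subdirectory per label name under `root` and writes each image
#' as an 8-bit grayscale (or RGB) PNG named after its id. Writing is
#' deterministic: regenerating with the same seed produces byte-identical
#' files. [load_image_folder()] round-trips the result exactly.
#'
#' @param ds a `labeled_image_set` with decodable pixels.
#' @param root output directory (created if missing).
#' @return invisibly, `root`.
#' @export
write_image_folder <- function(ds, root) {
  stopifnot(inherits(ds, "labeled_image_set"))
  for (nm in ds$label_names) {
    dir.create(file.path(root, nm), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n_images(ds))) {
    px <- get_pixels(ds, i)
    fname <- paste0(gsub("[/\\\\]", "_", ds$ids[i]), ".png")
    png::writePNG(px / 255,
                  file.path(root, ds$label_names[ds$labels[i] + 1L], fname))
  }
  invisible(root)
}
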