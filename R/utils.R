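# Internal helpers: rounding, logging, and bilinear image resampling.

# Round half away from zero (Table-style percentage printing, e.g. 2.25 -> 2.3),
# unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' @importFrom withr with_seed
NULL

# Convert an H x W x C array (or H x W matrix) to an H x W grayscale matrix
# using the standard luma weights. 1-channel arrays are dropped to a matrix;
# pixel scale is preserved.
to_gray <- function(px) {
  if (is.matrix(px)) return(px)
  d <- dim(px)
  if (length(d) == 2L) return(matrix(px, d[1], d[2]))
  if (length(d) == 3L && d[3] == 1L) return(px[, , 1L])
  if (length(d) == 3L && d[3] >= 3L) {
    return(0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L])
  }
  stop("unsupported pixel array with dimensions ", paste(d, collapse = "x"))
}

# Sample a matrix at fractional (row, col) coordinates with bilinear
# interpolation; coordinates outside the image clamp to the border, so
# out-of-frame reads take the nearest border value.
bilinear_sample <- function(img, row_coord, col_coord) {
  h <- nrow(img)
  w <- ncol(img)
  y <- pmin(pmax(row_coord, 1), h)
  x <- pmin(pmax(col_coord, 1), w)
  y0 <- floor(y)
  x0 <- floor(x)
  y1 <- pmin(y0 + 1, h)
  x1 <- pmin(x0 + 1, w)
  fy <- y - y0
  fx <- x - x0
  # column-major linear indices
  i00 <- (x0 - 1) * h + y0
  i01 <- (x1 - 1) * h + y0
  i10 <- (x0 - 1) * h + y1
  i11 <- (x1 - 1) * h + y1
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img)
  w <- ncol(img)
  ys <- if (out_h == 1L) (h + 1) / 2 else seq(1, h, length.out = out_h)
  xs <- if (out_w == 1L) (w + 1) / 2 else seq(1, w, length.out = out_w)
  grid_y <- rep(ys, times = out_w)
  grid_x <- rep(xs, each = out_h)
  matrix(bilinear_sample(img, grid_y, grid_x), out_h, out_w)
}

# Rotate about the image centre by `angle_deg` (counter-clockwise in standard
# x/y convention) with bilinear interpolation; border pixels extend outward.
rotate_channel <- function(img, angle_deg) {
  h <- nrow(img)
  w <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  rr <- rep(seq_len(h), times = w) - cy
  cc <- rep(seq_len(w), each = h) - cx
  src_r <- cos(th) * rr - sin(th) * cc + cy
  src_c <- sin(th) * rr + cos(th) * cc + cx
  matrix(bilinear_sample(img, src_r, src_c), h, w)
}

apply_per_channel <- function(px, f) {
  if (is.matrix(px)) return(f(px))
  out <- px
  for (ch in seq_len(dim(px)[3])) out[, , ch] <- f(px[, , ch])
  out
}

clip_pixels <- function(px, lo = 0, hi = 255) {
  px[px < lo] <- lo
  px[px > hi] <- hi
  px
}
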