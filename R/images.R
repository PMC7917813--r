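#' Image containers
#'
#' The package works on two plain-array image representations:
#' a *gray image* is a numeric `H x W` matrix of luminance values in
#' `[0, 1]` (rows index y, columns index x, both 0-based in the box
#' convention used by [bbox()]); a *color image* is an `H x W x 3`
#' numeric array of 8-bit channel intensities in `[0, 255]`.
#' Constructors validate and tag the arrays so downstream operations
#' can dispatch and check invariants cheaply.
#'
#' @param pixels numeric matrix (gray) or `H x W x 3` array (color).
#' @return An object of class `gray_image` (a matrix) or `color_image`
#'   (a 3-d array).
#' @examples
#' g <- gray_image(matrix(runif(64 * 32), 32, 64))
#' dim(g)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("gray_image: `pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("gray_image: image must have positive dimensions", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("gray_image: pixel values must be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("gray_image: pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @export
color_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("color_image: `pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("color_image: image must have positive dimensions", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("color_image: channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = c("color_image", "array"))
}

#' @rdname gray_image
#' @export
is_gray_image <- function(pixels) inherits(pixels, "gray_image")

#' @rdname gray_image
#' @export
is_color_image <- function(pixels) inherits(pixels, "color_image")

as_plain_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

#' Read and write images as PNG
#'
#' Thin wrappers over the \pkg{png} package. `read_image` returns a
#' `gray_image` for single-channel files and a `color_image` otherwise
#' (an alpha channel, if present, is dropped).
#'
#' @param path file path to a PNG image.
#' @param img a `gray_image` or `color_image`.
#' @return `read_image`: a `gray_image` or `color_image`;
#'   `write_image`: `path`, invisibly.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) {
    return(gray_image(px))
  }
  if (dim(px)[3] >= 3L) {
    return(color_image(round(px[, , 1:3, drop = FALSE] * 255)))
  }
  gray_image(px[, , 1])
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  if (is_gray_image(img)) {
    png::writePNG(as_plain_matrix(img), target = path)
  } else if (is_color_image(img)) {
    a <- unclass(img)
    attr(a, "class") <- NULL
    png::writePNG(a / 255, target = path)
  } else {
    stop("write_image: not an image object", call. = FALSE)
  }
  invisible(path)
}

# Reflect-pad a matrix by `k` pixels on every side (symmetric with edge
# duplication: ... c b a | a b c ...). Used by all convolutions.
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- c(pmin(k:1, h), seq_len(h), h + 1L - pmin(1:k, h))
  ci <- c(pmin(k:1, w), seq_len(w), w + 1L - pmin(1:k, w))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with an odd-sized kernel, reflect borders, implemented
# as a sum of shifted copies (kernels here are always small).
convolve2d_reflect <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  p <- pad_reflect(m, max(ry, rx))
  off <- max(ry, rx)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    dy <- i - 1L - ry
    for (j in seq_len(kw)) {
      kv <- kernel[i, j]
      if (kv == 0) next
      dx <- j - 1L - rx
      out <- out + kv * p[(off + 1L + dy):(off + h + dy),
                          (off + 1L + dx):(off + w + dx), drop = FALSE]
    }
  }
  out
}

# Row-resampling weight matrix mapping n_in samples onto n_out by exact
# area (box) averaging over the fractional overlap of output and input
# pixel intervals. W %*% x resamples columns of length n_in to n_out.
area_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    lo <- (o - 1) * scale
    hi <- o * scale
    i0 <- floor(lo) + 1L
    i1 <- min(ceiling(hi), n_in)
    for (i in i0:i1) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[o, i] <- ov / scale
    }
  }
  W
}

# Bilinear weight matrix (align-centers convention), for upscaling.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5
    i0 <- floor(src)
    f <- src - i0
    a <- min(max(i0 + 1, 1L), n_in)
    b <- min(max(i0 + 2, 1L), n_in)
    W[o, a] <- W[o, a] + (1 - f)
    W[o, b] <- W[o, b] + f
  }
  W
}

# Resample a matrix to (h_out, w_out); area averaging when shrinking
# along an axis, bilinear when growing.
resample_matrix <- function(m, h_out, w_out) {
  h <- nrow(m); w <- ncol(m)
  Wr <- if (h_out == h) diag(h) else if (h_out < h) area_weights(h, h_out)
        else bilinear_weights(h, h_out)
  Wc <- if (w_out == w) diag(w) else if (w_out < w) area_weights(w, w_out)
        else bilinear_weights(w, w_out)
  Wr %*% m %*% t(Wc)
}
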