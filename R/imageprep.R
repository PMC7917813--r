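#' Convert a color image to luminance
#'
#' BT.601 luma conversion: `Y = 0.299 R + 0.587 G + 0.114 B`, rescaled
#' from 8-bit channels to `[0, 1]`. Night-time infrared footage is
#' effectively single-channel, so the choice of luma weights only
#' matters for daytime color frames.
#'
#' @param img a `color_image`.
#' @return A `gray_image` with the same height and width.
#' @examples
#' im <- color_image(array(255, c(4, 4, 3)))
#' range(to_grayscale(im)) # all 1
#' @export
to_grayscale <- function(img) {
  if (!is_color_image(img)) {
    stop("to_grayscale: expected a color_image", call. = FALSE)
  }
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray_image(pmin(pmax(y / 255, 0), 1))
}

#' Gaussian smoothing
#'
#' Convolution with a normalized 2D Gaussian kernel over a
#' `kernel_size x kernel_size` neighborhood (default 3x3, sigma 0.5 —
#' the noise-suppression setting used before face detection). Borders
#' are handled by reflection, so constant images are exact fixed
#' points and total intensity is conserved.
#'
#' @param img a `gray_image`.
#' @param kernel_size odd integer kernel side length.
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return The smoothed `gray_image`.
#' @export
gaussian_smooth <- function(img, kernel_size = 3L, sigma = 0.5) {
  if (!is_gray_image(img)) {
    stop("gaussian_smooth: expected a gray_image", call. = FALSE)
  }
  if (kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("gaussian_smooth: kernel_size must be odd and >= 1", call. = FALSE)
  }
  if (sigma <= 0) stop("gaussian_smooth: sigma must be > 0", call. = FALSE)
  k <- gaussian_kernel(kernel_size, sigma)
  out <- convolve2d_reflect(as_plain_matrix(img), k)
  gray_image(pmin(pmax(out, 0), 1))
}

gaussian_kernel <- function(kernel_size, sigma) {
  r <- (kernel_size - 1L) %/% 2L
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Light compensation for in-vehicle frames: the image is divided into
#' a grid of tiles, a clipped (contrast-limited) histogram equalization
#' mapping is computed per tile, and every pixel is remapped by
#' bilinear interpolation between the four neighboring tile mappings.
#' Clipped histogram excess is redistributed iteratively so that no bin
#' exceeds the clip limit. Each channel of a color image is equalized
#' independently; a `gray_image` is equalized as a single channel.
#'
#' @param img a `color_image` or `gray_image`.
#' @param clip_limit clip limit as a multiple of the mean bin count
#'   (`> 0`; larger means more contrast enhancement).
#' @param tiles integer vector `c(nx, ny)`: tile grid size.
#' @param bins number of histogram bins.
#' @return An image of the same class and dimensions.
#' @export
clahe_equalize <- function(img, clip_limit = 2.0, tiles = c(8L, 8L),
                           bins = 256L) {
  if (clip_limit <= 0) {
    stop("clahe_equalize: clip_limit must be > 0", call. = FALSE)
  }
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L)) {
    stop("clahe_equalize: tiles must be two integers >= 1", call. = FALSE)
  }
  if (is_gray_image(img)) {
    out <- clahe_channel(as_plain_matrix(img), clip_limit, tiles, bins)
    return(gray_image(pmin(pmax(out, 0), 1)))
  }
  if (!is_color_image(img)) {
    stop("clahe_equalize: expected a color_image or gray_image", call. = FALSE)
  }
  out <- unclass(img)
  attr(out, "class") <- NULL
  for (ch in 1:3) {
    eq <- clahe_channel(out[, , ch] / 255, clip_limit, tiles, bins)
    out[, , ch] <- pmin(pmax(eq * 255, 0), 255)
  }
  color_image(out)
}

# CLAHE on one [0,1] channel. Tile mappings are CDFs of clip-limited
# histograms; pixels are remapped by bilinear interpolation between the
# four surrounding tile mappings (tile centers as interpolation nodes,
# clamped at the image border).
clahe_channel <- function(m, clip_limit, tiles, bins) {
  h <- nrow(m); w <- ncol(m)
  nx <- min(tiles[1], w); ny <- min(tiles[2], h)
  # tile boundaries (as even as possible)
  xb <- round(seq(0, w, length.out = nx + 1))
  yb <- round(seq(0, h, length.out = ny + 1))
  bin_of <- pmin(pmax(floor(m * bins) + 1L, 1L), bins)
  luts <- array(0, c(ny, nx, bins))
  for (ty in seq_len(ny)) {
    for (tx in seq_len(nx)) {
      sub <- bin_of[(yb[ty] + 1L):yb[ty + 1L], (xb[tx] + 1L):xb[tx + 1L]]
      hst <- tabulate(sub, nbins = bins)
      n <- length(sub)
      clip <- clip_limit * n / bins
      hst <- clip_redistribute(hst, clip)
      cdf <- cumsum(hst) / n
      # map bin k to the CDF midpoint of its mass for symmetry
      luts[ty, tx, ] <- cdf - hst / (2 * n)
    }
  }
  # tile centers in pixel coordinates (1-based continuous)
  cx <- (xb[-1] + xb[-length(xb)] + 1) / 2
  cy <- (yb[-1] + yb[-length(yb)] + 1) / 2
  # per-row / per-column interpolation indices and weights
  iy <- findInterval(seq_len(h), cy)               # 0..ny
  iy0 <- pmin(pmax(iy, 1L), ny); iy1 <- pmin(iy + 1L, ny)
  fy <- ifelse(iy0 == iy1, 0,
               (seq_len(h) - cy[iy0]) / (cy[iy1] - cy[iy0]))
  fy <- pmin(pmax(fy, 0), 1)
  ix <- findInterval(seq_len(w), cx)
  ix0 <- pmin(pmax(ix, 1L), nx); ix1 <- pmin(ix + 1L, nx)
  fx <- ifelse(ix0 == ix1, 0,
               (seq_len(w) - cx[ix0]) / (cx[ix1] - cx[ix0]))
  fx <- pmin(pmax(fx, 0), 1)

  Ry <- matrix(rep(iy0, w), h, w); Ry1 <- matrix(rep(iy1, w), h, w)
  Cx <- matrix(rep(ix0, each = h), h, w); Cx1 <- matrix(rep(ix1, each = h), h, w)
  Fy <- matrix(rep(fy, w), h, w); Fx <- matrix(rep(fx, each = h), h, w)
  B <- bin_of
  v00 <- luts[cbind(c(Ry), c(Cx), c(B))]
  v01 <- luts[cbind(c(Ry), c(Cx1), c(B))]
  v10 <- luts[cbind(c(Ry1), c(Cx), c(B))]
  v11 <- luts[cbind(c(Ry1), c(Cx1), c(B))]
  out <- (1 - c(Fy)) * ((1 - c(Fx)) * v00 + c(Fx) * v01) +
         c(Fy) * ((1 - c(Fx)) * v10 + c(Fx) * v11)
  matrix(out, h, w)
}

# Clip histogram bins at `clip` and spread the excess uniformly,
# repeating until the leftover is negligible (no bin above the limit
# by more than a vanishing amount).
clip_redistribute <- function(hst, clip) {
  for (i in 1:16) {
    excess <- sum(pmax(hst - clip, 0))
    if (excess <= 1e-9 * sum(hst)) break
    hst <- pmin(hst, clip) + excess / length(hst)
  }
  hst
}

#' Downscale an image
#'
#' Resolution reduction by exact area averaging, used to trade spatial
#' detail for throughput after light compensation. `factor = 1` is the
#' identity (the default: no downscaling).
#'
#' @param img a `gray_image` or `color_image`.
#' @param factor scale factor in `(0, 1]`.
#' @return An image of the same class with dimensions
#'   `round(dim * factor)` (at least 1 pixel).
#' @export
downscale <- function(img, factor = 1.0) {
  if (!is.numeric(factor) || length(factor) != 1L ||
      factor <= 0 || factor > 1) {
    stop("downscale: factor must be in (0, 1]", call. = FALSE)
  }
  if (factor == 1.0) return(img)
  if (is_gray_image(img)) {
    h2 <- max(1L, as.integer(round(nrow(img) * factor)))
    w2 <- max(1L, as.integer(round(ncol(img) * factor)))
    out <- resample_matrix(as_plain_matrix(img), h2, w2)
    return(gray_image(pmin(pmax(out, 0), 1)))
  }
  if (is_color_image(img)) {
    h2 <- max(1L, as.integer(round(dim(img)[1] * factor)))
    w2 <- max(1L, as.integer(round(dim(img)[2] * factor)))
    out <- array(0, c(h2, w2, 3))
    for (ch in 1:3) out[, , ch] <- resample_matrix(img[, , ch], h2, w2)
    return(color_image(pmin(pmax(out, 0), 255)))
  }
  stop("downscale: not an image object", call. = FALSE)
}

#' Preprocess a frame
#'
#' The standard preprocessing chain applied before region-of-interest
#' detection, in order: Gaussian noise suppression (each channel),
#' CLAHE light compensation (each channel independently), grayscale
#' conversion, optional downscaling. Parameters come from a pipeline
#' configuration, see [default_config()].
#'
#' @param img a `color_image` or `gray_image`.
#' @param config a pipeline configuration list.
#' @return A preprocessed `gray_image`.
#' @export
preprocess_frame <- function(img, config = default_config()) {
  ks <- config$preprocess.gaussian_kernel
  sg <- config$preprocess.gaussian_sigma
  if (is_color_image(img)) {
    k <- gaussian_kernel(ks, sg)
    px <- unclass(img)
    attr(px, "class") <- NULL
    for (ch in 1:3) {
      px[, , ch] <- pmin(pmax(convolve2d_reflect(px[, , ch], k), 0), 255)
    }
    img <- color_image(px)
  } else {
    img <- gaussian_smooth(img, kernel_size = ks, sigma = sg)
  }
  img <- clahe_equalize(img,
    clip_limit = config$preprocess.clahe_clip,
    tiles = config$preprocess.clahe_tiles
  )
  if (is_color_image(img)) img <- to_grayscale(img)
  downscale(img, config$preprocess.downscale)
}
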