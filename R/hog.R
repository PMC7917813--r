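#' Per-pixel gradient magnitude and orientation
#'
#' Computes the gradient field of an eye patch: magnitude
#' `rho = sqrt(Lx^2 + Ly^2)` and unsigned orientation
#' `gamma = atan2(Ly, Lx) mod pi` in `[0, pi)`. Derivatives `Lx`, `Ly`
#' are taken either with the centered difference mask `[-1, 0, 1]`
#' (the default, applied along x and transposed along y) or with
#' first-order Gaussian-derivative kernels at scale `sigma`. Borders
#' are reflected. Where `rho = 0` the orientation is undefined and set
#' to 0 by convention (it carries no vote mass).
#'
#' @param patch a `gray_image` (or numeric matrix in `[0, 1]`), at
#'   least 3x3.
#' @param method `"central"` or `"gaussian"`.
#' @param sigma scale of the Gaussian-derivative kernels (used only
#'   for `method = "gaussian"`).
#' @return A list of class `gradient_field` with matrices `rho`
#'   (non-negative) and `gamma` (in `[0, pi)`), same dimensions as the
#'   patch.
#' @export
compute_gradients <- function(patch, method = c("central", "gaussian"),
                              sigma = 1.0) {
  method <- match.arg(method)
  m <- if (is_gray_image(patch)) as_plain_matrix(patch) else patch
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 3L) {
    stop("compute_gradients: patch must be at least 3x3", call. = FALSE)
  }
  if (method == "central") {
    kx <- matrix(c(-1, 0, 1), 1, 3) # I(x+1) - I(x-1)
    lx <- convolve2d_reflect(m, kx)
    ly <- convolve2d_reflect(m, t(kx))
  } else {
    if (sigma <= 0) stop("compute_gradients: sigma must be > 0", call. = FALSE)
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    xs <- -r:r
    g <- exp(-xs^2 / (2 * sigma^2))
    g <- g / sum(g)
    dg <- xs / sigma^2 * exp(-xs^2 / (2 * sigma^2))
    # normalize the discrete derivative so a unit-slope ramp responds
    # with exactly 1 (the truncated sampled kernel would be ~0.5% off)
    dg <- dg / sum(xs * dg)
    # separable: d/dx Gaussian = dg(x) * g(y)
    kx <- outer(g, dg)   # rows = y, cols = x
    lx <- convolve2d_reflect(m, kx)
    ly <- convolve2d_reflect(m, t(kx))
  }
  rho <- sqrt(lx^2 + ly^2)
  gamma <- atan2(ly, lx) %% pi
  # orientation is circular with period pi: values within float noise
  # of pi are the same direction as 0
  gamma[gamma >= pi - 1e-9] <- 0
  gamma[rho == 0] <- 0
  structure(list(rho = rho, gamma = gamma), class = "gradient_field")
}

#' Anti-aliased orientation vote weights
#'
#' Splits a single orientation `gamma` in `[0, pi)` between the two
#' nearest of `m` circular orientation bins (bin width `pi/m`, centers
#' at `(k + 0.5) * pi / m`, wrap-around modulo `m` because orientation
#' is periodic with period `pi`). The split is circular bilinear
#' interpolation: an orientation at a bin center puts all its mass in
#' that bin, one at a bin boundary splits evenly. Weights are
#' non-negative and sum to exactly 1.
#'
#' @param gamma orientation(s) in `[0, pi)` (vectorized).
#' @param m number of orientation bins (`>= 2`).
#' @return A list with integer vectors `b0`, `b1` (0-based bin
#'   indices) and numeric vectors `w0`, `w1`.
#' @examples
#' vote_weights(pi / 16, m = 8) # center of bin 0: all mass to bin 0
#' @export
vote_weights <- function(gamma, m = 8L) {
  if (m < 2L) stop("vote_weights: m must be >= 2", call. = FALSE)
  if (any(gamma < 0 | gamma >= pi)) {
    stop("vote_weights: gamma must lie in [0, pi)", call. = FALSE)
  }
  width <- pi / m
  # position in units of bins, measured from the center of bin 0
  u <- gamma / width - 0.5
  b0 <- floor(u)
  w1 <- u - b0                    # fraction toward the upper neighbor
  w0 <- 1 - w1
  list(
    b0 = as.integer(b0 %% m),
    b1 = as.integer((b0 + 1) %% m),
    w0 = w0,
    w1 = w1
  )
}

#' Per-cell orientation histograms
#'
#' Partitions the gradient field into non-overlapping square cells
#' (default 8x8 pixels) and accumulates each pixel's gradient
#' magnitude into `m` orientation bins, split between the two nearest
#' bins by [vote_weights()]. Total histogram mass equals the total
#' gradient magnitude (mass conservation).
#'
#' @param grad a `gradient_field` from [compute_gradients()].
#' @param cell_size cell side length in pixels; field dimensions must
#'   be exact multiples.
#' @param m number of orientation bins.
#' @return An object of class `cell_grid`: an array `Cy x Cx x m` of
#'   non-negative vote masses with attributes `cell_size` and `m`.
#' @export
cell_histograms <- function(grad, cell_size = 8L, m = 8L) {
  if (!inherits(grad, "gradient_field")) {
    stop("cell_histograms: expected a gradient_field", call. = FALSE)
  }
  h <- nrow(grad$rho); w <- ncol(grad$rho)
  if (h %% cell_size != 0L || w %% cell_size != 0L) {
    stop("cell_histograms: field dimensions must be multiples of cell_size",
         call. = FALSE)
  }
  cy <- h %/% cell_size; cx <- w %/% cell_size
  vw <- vote_weights(c(grad$gamma), m)
  rho <- c(grad$rho)
  # cell index per pixel (column-major layout of the field matrix)
  py <- rep(seq_len(h), times = w)
  px <- rep(seq_len(w), each = h)
  cell <- ((py - 1L) %/% cell_size) + cy * ((px - 1L) %/% cell_size) # 0-based
  idx0 <- cell + cy * cx * vw$b0 + 1L
  idx1 <- cell + cy * cx * vw$b1 + 1L
  acc <- rowsum(c(rho * vw$w0, rho * vw$w1), group = c(idx0, idx1))
  hist <- numeric(cy * cx * m)
  hist[as.integer(rownames(acc))] <- acc[, 1]
  structure(array(hist, c(cy, cx, m)),
            cell_size = as.integer(cell_size), m = as.integer(m),
            class = "cell_grid")
}
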