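# Canonical within-block cell pairs, raster order TL, TR, BL, BR:
# TL-TR, TL-BL, TL-BR, TR-BL, TR-BR, BL-BR. Comparison is first vs
# second, and the order is part of the descriptor format.
block_pairs <- function() {
  matrix(c(1L, 2L, 1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L, 3L, 4L),
         ncol = 2L, byrow = TRUE)
}

#' Binary comparison of two shifted orientation histograms
#'
#' For two `m`-bin orientation histograms `v1`, `v2`, computes the
#' `m x m` bit pattern `b(k, eps) = 1` iff
#' `v1[k] >= v2[(k + eps) mod m]`, over all cyclic shifts
#' `eps = 0..m-1` and bins `k = 0..m-1`. Ties yield 1 (">=").
#' Bits are ordered shift-major: all `k` for `eps = 0`, then
#' `eps = 1`, and so on.
#'
#' @param v1,v2 numeric non-negative histograms of equal length `m`.
#' @param m number of bins (defaults to `length(v1)`).
#' @return An integer vector of `m * m` bits in `{0, 1}`.
#' @export
binarize_pair <- function(v1, v2, m = length(v1)) {
  if (length(v1) != m || length(v2) != m) {
    stop("binarize_pair: histograms must both have length m", call. = FALSE)
  }
  bits <- integer(m * m)
  for (eps in 0:(m - 1L)) {
    shifted <- v2[((seq_len(m) - 1L + eps) %% m) + 1L]
    bits[eps * m + seq_len(m)] <- as.integer(v1 >= shifted)
  }
  bits
}

#' Binarized shifted-orientation HOG descriptor (BOSH)
#'
#' The improved HOG descriptor: cells are grouped into 2x2-cell blocks
#' with a 1-cell stride (each interior cell is covered by four
#' blocks); within each block, all 6 unordered cell pairs in canonical
#' raster order (TL-TR, TL-BL, TL-BR, TR-BL, TR-BR, BL-BR) are
#' compared with [binarize_pair()] under all `m` cyclic orientation
#' shifts. Bits are concatenated block-major (blocks in raster order),
#' then pair-major, then shift-major. Because every bit is a
#' comparison between two vote masses, the descriptor is invariant to
#' any common positive scaling of the image — and hence to affine
#' illumination changes `a * I + c` — so no block normalization is
#' applied (it would be redundant).
#'
#' @param grid a `cell_grid` from [cell_histograms()], at least 2x2
#'   cells.
#' @return An object of class `bosh_descriptor`: an integer 0/1 vector
#'   with a `layout` attribute describing the geometry (see
#'   [descriptor_length()]).
#' @export
extract_bosh <- function(grid) {
  if (!inherits(grid, "cell_grid")) {
    stop("extract_bosh: expected a cell_grid", call. = FALSE)
  }
  d <- dim(grid)
  cy <- d[1]; cx <- d[2]; m <- d[3]
  if (cy < 2L || cx < 2L) {
    stop("extract_bosh: need at least 2x2 cells", call. = FALSE)
  }
  pairs <- block_pairs()
  nby <- cy - 1L; nbx <- cx - 1L
  bits <- integer(nby * nbx * nrow(pairs) * m * m)
  pos <- 0L
  chunk <- m * m
  for (by in seq_len(nby)) {        # raster order: rows of blocks
    for (bx in seq_len(nbx)) {
      # cell histograms of the 2x2 block, raster order TL TR BL BR
      cells <- list(
        grid[by, bx, ], grid[by, bx + 1L, ],
        grid[by + 1L, bx, ], grid[by + 1L, bx + 1L, ]
      )
      for (p in seq_len(nrow(pairs))) {
        bits[pos + seq_len(chunk)] <-
          binarize_pair(cells[[pairs[p, 1L]]], cells[[pairs[p, 2L]]], m)
        pos <- pos + chunk
      }
    }
  }
  structure(bits,
    layout = descriptor_layout(cy, cx, attr(grid, "cell_size"), m, "bosh"),
    class = "bosh_descriptor"
  )
}

#' Baseline real-valued HOG descriptor
#'
#' The conventional HOG feature vector used as the comparison
#' baseline: per 2x2-cell block (1-cell stride, raster order), the 4
#' cell histograms are concatenated (raster order) and the block
#' vector is L2-normalized with guard `eps_norm`; block vectors are
#' concatenated in raster order.
#'
#' @param grid a `cell_grid`, at least 2x2 cells.
#' @param eps_norm normalization guard added in quadrature.
#' @return An object of class `hog_descriptor`: a numeric vector with
#'   a `layout` attribute.
#' @export
extract_hog_baseline <- function(grid, eps_norm = 1e-6) {
  if (!inherits(grid, "cell_grid")) {
    stop("extract_hog_baseline: expected a cell_grid", call. = FALSE)
  }
  d <- dim(grid)
  cy <- d[1]; cx <- d[2]; m <- d[3]
  if (cy < 2L || cx < 2L) {
    stop("extract_hog_baseline: need at least 2x2 cells", call. = FALSE)
  }
  nby <- cy - 1L; nbx <- cx - 1L
  out <- numeric(nby * nbx * 4L * m)
  pos <- 0L
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      v <- c(grid[by, bx, ], grid[by, bx + 1L, ],
             grid[by + 1L, bx, ], grid[by + 1L, bx + 1L, ])
      nrm <- sqrt(sum(v^2) + eps_norm^2)
      out[pos + seq_along(v)] <- v / nrm
      pos <- pos + length(v)
    }
  }
  structure(out,
    layout = descriptor_layout(cy, cx, attr(grid, "cell_size"), m, "hog"),
    class = "hog_descriptor"
  )
}

descriptor_layout <- function(cy, cx, cell_size, m, scheme) {
  list(
    cells_y = as.integer(cy), cells_x = as.integer(cx),
    cell_size = as.integer(cell_size), m = as.integer(m),
    scheme = scheme,
    patch_w = as.integer(cx * cell_size), patch_h = as.integer(cy * cell_size)
  )
}

#' Descriptor length from geometry
#'
#' Closed-form length of the descriptor produced from a patch of the
#' given dimensions: with `Cy x Cx` cells there are
#' `(Cy - 1) * (Cx - 1)` overlapping 2x2 blocks; the BOSH scheme emits
#' `6 * m * m` bits per block, the baseline HOG scheme `4 * m` values
#' per block.
#'
#' @param patch_dims integer `c(width, height)` of the patch in
#'   pixels.
#' @param cell_size cell side in pixels (dims must divide evenly).
#' @param m number of orientation bins.
#' @param scheme `"bosh"` or `"hog"`.
#' @return Integer descriptor length.
#' @examples
#' descriptor_length(c(64, 32), 8, 8, "bosh") # 8064
#' @export
descriptor_length <- function(patch_dims, cell_size = 8L, m = 8L,
                              scheme = c("bosh", "hog")) {
  scheme <- match.arg(scheme)
  w <- patch_dims[1]; h <- patch_dims[2]
  if (w %% cell_size != 0L || h %% cell_size != 0L) {
    stop("descriptor_length: dims must be multiples of cell_size",
         call. = FALSE)
  }
  cx <- w %/% cell_size; cy <- h %/% cell_size
  if (cx < 2L || cy < 2L) {
    stop("descriptor_length: need at least 2x2 cells", call. = FALSE)
  }
  nblocks <- (cy - 1L) * (cx - 1L)
  if (scheme == "bosh") {
    as.integer(nblocks * nrow(block_pairs()) * m * m)
  } else {
    as.integer(nblocks * 4L * m)
  }
}

#' Full patch-to-descriptor pipeline
#'
#' Convenience wrapper: gradients, cell histograms and descriptor
#' extraction for a canonical eye patch, driven by a pipeline
#' configuration.
#'
#' @param patch an `eye_patch` or `gray_image`.
#' @param features `"bosh"` or `"hog"`.
#' @param config pipeline configuration, see [default_config()].
#' @return A `bosh_descriptor` or `hog_descriptor`.
#' @export
patch_descriptor <- function(patch, features = c("bosh", "hog"),
                             config = default_config()) {
  features <- match.arg(features)
  grad <- compute_gradients(patch,
    method = config$hog.gradient_method,
    sigma = config$hog.gradient_sigma
  )
  grid <- cell_histograms(grad,
    cell_size = config$hog.cell_size,
    m = config$hog.bins
  )
  if (features == "bosh") extract_bosh(grid) else extract_hog_baseline(grid)
}
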