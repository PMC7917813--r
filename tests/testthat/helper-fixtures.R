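# Shared fixtures and independent oracles for the test suite.

# Random gray patch (plain matrix in [0,1]); seeded for reproducibility.
random_patch <- function(seed, h = 32L, w = 64L) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

random_gradient_field <- function(seed, h = 16L, w = 16L) {
  set.seed(seed)
  structure(
    list(rho = matrix(rexp(h * w), h, w),
         gamma = matrix(runif(h * w, 0, pi - 1e-9), h, w)),
    class = "gradient_field"
  )
}

# Independent brute-force BOSH reference: plain nested loops over
# blocks (raster), the six canonical pairs, shifts and bins, reading
# histograms straight out of the cell grid. Shares no code with
# extract_bosh/binarize_pair.
bf_bosh <- function(grid) {
  d <- dim(grid)
  cy <- d[1]; cx <- d[2]; m <- d[3]
  pair_idx <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  bits <- integer(0)
  for (by in 1:(cy - 1)) {
    for (bx in 1:(cx - 1)) {
      cells <- list(grid[by, bx, ], grid[by, bx + 1, ],
                    grid[by + 1, bx, ], grid[by + 1, bx + 1, ])
      for (pr in pair_idx) {
        v1 <- cells[[pr[1]]]; v2 <- cells[[pr[2]]]
        for (eps in 0:(m - 1)) {
          for (k in 0:(m - 1)) {
            bits <- c(bits, if (v1[k + 1] >= v2[((k + eps) %% m) + 1]) 1L
                      else 0L)
          }
        }
      }
    }
  }
  bits
}

# Full patch -> BOSH bits using package operations (no smoothing).
raw_bosh <- function(patch, cell_size = 8L, m = 8L) {
  grid <- cell_histograms(compute_gradients(patch), cell_size, m)
  as.integer(extract_bosh(grid))
}

sample_labels <- function(samples) vapply(samples, `[[`, "", "label")
sample_scenarios <- function(samples) vapply(samples, `[[`, "", "scenario")
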