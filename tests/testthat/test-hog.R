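test_that("gradients vanish on constants and match ramps analytically", {
  g0 <- compute_gradients(matrix(0.7, 8, 8))
  expect_true(all(g0$rho == 0))
  expect_true(all(g0$gamma == 0))

  w <- 16L
  ramp_x <- matrix(rep((seq_len(w) - 1) / w, each = 8), 8, w)
  gx <- compute_gradients(ramp_x)
  interior <- gx$rho[3:6, 3:(w - 2)]
  expect_equal(as.numeric(interior), rep(2 / w, length(interior)),
               tolerance = 1e-12)
  expect_equal(as.numeric(gx$gamma[3:6, 3:(w - 2)]),
               rep(0, length(interior)), tolerance = 1e-12)

  ramp_y <- t(ramp_x)
  gy <- compute_gradients(ramp_y)
  expect_equal(as.numeric(gy$gamma[3:(w - 2), 3:6]),
               rep(pi / 2, 4 * (w - 4)), tolerance = 1e-12)

  expect_error(compute_gradients(matrix(0, 2, 2)), "3x3")
})

test_that("gaussian-derivative gradients agree with central on smooth ramps", {
  w <- 24L
  ramp <- matrix(rep((seq_len(w) - 1) / w, each = 24), 24, w)
  g <- compute_gradients(ramp, method = "gaussian", sigma = 1.0)
  # interior gradient of a unit-slope ramp under a normalized
  # derivative-of-Gaussian kernel is the slope itself
  expect_equal(as.numeric(g$gamma[8:16, 8:16]), rep(0, 81), tolerance = 1e-9)
  expect_equal(as.numeric(g$rho[8:16, 8:16]), rep(1 / w, 81),
               tolerance = 1e-6)
})

test_that("vote weights split orientations between the two nearest bins", {
  vw <- vote_weights(pi / 16, 8L) # center of bin 0
  expect_identical(c(vw$b0, vw$b1), c(0L, 1L))
  expect_equal(c(vw$w0, vw$w1), c(1, 0), tolerance = 1e-12)

  vw <- vote_weights(0, 8L) # left edge of bin 0: split with bin 7
  expect_identical(c(vw$b0, vw$b1), c(7L, 0L))
  expect_equal(c(vw$w0, vw$w1), c(0.5, 0.5), tolerance = 1e-12)

  vw <- vote_weights(pi / 8, 8L) # boundary bin 0 / bin 1
  expect_identical(c(vw$b0, vw$b1), c(0L, 1L))
  expect_equal(c(vw$w0, vw$w1), c(0.5, 0.5), tolerance = 1e-12)

  expect_error(vote_weights(pi, 8L), "\\[0, pi\\)")
  expect_error(vote_weights(0.1, 1L), "m must be")
})

test_that("vote weights are the sign-safe form of the bin-offset weight", {
  # alpha = b + 0.5 - gamma/(pi/m) for the bin b containing gamma;
  # |alpha| goes to the neighbor on gamma's side, 1-|alpha| stays.
  set.seed(31)
  m <- 8L
  width <- pi / m
  for (gamma in runif(200, 0, pi - 1e-12)) {
    b <- floor(gamma / width)
    alpha <- b + 0.5 - gamma / width
    vw <- vote_weights(gamma, m)
    own <- if (vw$b0 == b %% m) c(vw$w0, vw$w1) else c(vw$w1, vw$w0)
    expect_equal(own[1], 1 - abs(alpha), tolerance = 1e-12)
    expect_equal(own[2], abs(alpha), tolerance = 1e-12)
    neighbor <- if (alpha > 0) (b - 1) %% m else (b + 1) %% m
    other_bin <- if (vw$b0 == b %% m) vw$b1 else vw$b0
    if (abs(alpha) > 1e-9) expect_identical(other_bin, as.integer(neighbor))
  }
})

test_that("vote weights always sum to one and are non-negative", {
  set.seed(7)
  g <- runif(500, 0, pi - 1e-12)
  vw <- vote_weights(g, 8L)
  expect_true(all(vw$w0 >= 0 & vw$w1 >= 0))
  expect_equal(vw$w0 + vw$w1, rep(1, 500), tolerance = 0)
})

test_that("cell histograms conserve gradient mass", {
  zero <- structure(list(rho = matrix(0, 16, 16),
                         gamma = matrix(0, 16, 16)),
                    class = "gradient_field")
  expect_true(all(cell_histograms(zero) == 0))

  # single pixel, rho 3 at the center of bin 0
  f <- structure(list(rho = matrix(0, 8, 8), gamma = matrix(0, 8, 8)),
                 class = "gradient_field")
  f$rho[3, 5] <- 3; f$gamma[3, 5] <- pi / 16
  cg <- cell_histograms(f)
  expect_equal(as.numeric(cg[1, 1, ]), c(3, rep(0, 7)), tolerance = 1e-12)

  for (s in 1:50) {
    f <- random_gradient_field(s)
    cg <- cell_histograms(f)
    expect_lt(abs(sum(cg) - sum(f$rho)) / sum(f$rho), 1e-9)
    # per-cell mass equals per-cell sum of rho
    expect_equal(sum(cg[1, 2, ]), sum(f$rho[1:8, 9:16]), tolerance = 1e-9)
  }

  bad <- random_gradient_field(1, 10, 16)
  expect_error(cell_histograms(bad), "multiples")
})

test_that("cell histograms are linear in gradient magnitude", {
  f <- random_gradient_field(77)
  cg1 <- cell_histograms(f)
  f2 <- f; f2$rho <- 3.5 * f$rho
  cg2 <- cell_histograms(f2)
  expect_equal(as.numeric(cg2), 3.5 * as.numeric(cg1), tolerance = 1e-12)
})

test_that("rotating a ramp by 90 degrees shifts bins by m/2", {
  w <- 32L
  ramp <- matrix(rep((seq_len(w) - 1) / w, each = w), w, w)
  rot <- t(ramp)[w:1, ] # 90-degree rotation
  cg_a <- cell_histograms(compute_gradients(ramp))
  cg_b <- cell_histograms(compute_gradients(rot))
  # compare interior cells only (borders differ under reflection)
  a <- apply(cg_a[2:3, 2:3, , drop = FALSE], 3, sum)
  b <- apply(cg_b[2:3, 2:3, , drop = FALSE], 3, sum)
  expect_equal(a, b[c(5:8, 1:4)], tolerance = 1e-9)
})
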