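test_that("binarize_pair matches the shift-comparison definition", {
  # equal constant histograms: v >= v everywhere, all 64 bits set
  v <- rep(2, 8)
  expect_identical(binarize_pair(v, v), rep(1L, 64))

  expect_identical(binarize_pair(rep(0, 8), rep(1, 8)), rep(0L, 64))

  # independent nested-loop oracle on random integer histograms
  set.seed(21)
  for (i in 1:200) {
    v1 <- sample(0:9, 8, replace = TRUE)
    v2 <- sample(0:9, 8, replace = TRUE)
    expected <- integer(0)
    for (eps in 0:7) {
      for (k in 0:7) {
        expected <- c(expected,
                      if (v1[k + 1] >= v2[((k + eps) %% 8) + 1]) 1L else 0L)
      }
    }
    expect_identical(binarize_pair(v1, v2), expected)
  }

  expect_error(binarize_pair(rep(1, 8), rep(1, 7)), "length")
})

test_that("descriptor geometry gives the expected lengths", {
  expect_identical(descriptor_length(c(64, 32), 8, 8, "bosh"), 8064L)
  expect_identical(descriptor_length(c(16, 16), 8, 8, "bosh"), 384L)
  expect_identical(descriptor_length(c(64, 32), 8, 8, "hog"), 672L)
  expect_error(descriptor_length(c(60, 32), 8, 8, "bosh"), "multiples")
  expect_error(descriptor_length(c(8, 8), 8, 8, "bosh"), "2x2")

  expect_length(raw_bosh(random_patch(1)), 8064L)
  expect_length(raw_bosh(random_patch(2, 16, 16)), 384L)
  grid <- cell_histograms(compute_gradients(random_patch(3)))
  expect_length(extract_hog_baseline(grid), 672L)
})

test_that("extract_bosh equals the brute-force reference bit-for-bit", {
  for (s in 1:20) {
    grid <- cell_histograms(compute_gradients(random_patch(s, 24, 32)))
    expect_identical(as.integer(extract_bosh(grid)), bf_bosh(grid))
  }
})

test_that("identical cells repeat the single self-comparison pattern", {
  # uniform-gradient patch: every cell histogram identical
  w <- 32L
  ramp <- matrix(rep(seq_len(w) / w * 0.9, each = 16), 16, w)
  grid <- cell_histograms(compute_gradients(ramp))
  # force exact equality of cells (interior of a ramp is uniform but
  # borders are not; build the grid explicitly)
  h1 <- grid[1, 2, ]
  for (i in seq_len(dim(grid)[1])) {
    for (j in seq_len(dim(grid)[2])) grid[i, j, ] <- h1
  }
  bits <- as.integer(extract_bosh(grid))
  unit <- binarize_pair(h1, h1)
  expect_identical(bits, rep(unit, length(bits) / 64L))
})

test_that("BOSH is invariant to gain and offset on the raw patch", {
  p <- random_patch(10)
  ref <- raw_bosh(p)
  for (a in c(0.25, 4)) {
    expect_identical(raw_bosh(a * p), ref)
  }
  expect_identical(raw_bosh(p + 0.1), ref)
})

test_that("baseline HOG blocks are L2-normalized with a guard", {
  zero <- structure(array(0, c(4, 8, 8)), cell_size = 8L, m = 8L,
                    class = "cell_grid")
  expect_true(all(extract_hog_baseline(zero) == 0))

  for (s in 1:20) {
    grid <- cell_histograms(compute_gradients(random_patch(s)))
    v <- as.numeric(extract_hog_baseline(grid))
    norms <- vapply(seq_len(length(v) / 32L), function(b) {
      sqrt(sum(v[((b - 1) * 32 + 1):(b * 32)]^2))
    }, numeric(1))
    expect_true(all(norms == 0 | (norms >= 1 - 1e-4 & norms <= 1)))
  }
})

test_that("baseline HOG is invariant to positive gain", {
  p <- random_patch(14)
  a <- as.numeric(extract_hog_baseline(
    cell_histograms(compute_gradients(p))))
  b <- as.numeric(extract_hog_baseline(
    cell_histograms(compute_gradients(2 * p))))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("descriptor containers round-trip bits and values exactly", {
  descs <- lapply(1:5, function(s) {
    extract_bosh(cell_histograms(compute_gradients(random_patch(s, 16, 24))))
  })
  for (fmt in c("binary", "text")) {
    path <- withr::local_tempfile(fileext = ".desc")
    write_descriptors(descs, path, fmt)
    back <- read_descriptors(path, fmt)
    expect_identical(back$scheme, "bosh")
    for (i in 1:5) {
      expect_identical(as.integer(back$descriptors[[i]]),
                       as.integer(descs[[i]]))
    }
  }

  hdescs <- lapply(1:3, function(s) {
    extract_hog_baseline(
      cell_histograms(compute_gradients(random_patch(s, 16, 24))))
  })
  for (fmt in c("binary", "text")) {
    path <- withr::local_tempfile(fileext = ".desc")
    write_descriptors(hdescs, path, fmt)
    back <- read_descriptors(path, fmt)
    expect_identical(back$scheme, "hog")
    for (i in 1:3) {
      expect_equal(as.numeric(back$descriptors[[i]]),
                   as.numeric(hdescs[[i]]), tolerance = 0)
    }
  }
})

test_that("bit packing is MSB-first with header-recorded length", {
  bits <- c(1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L)
  raw <- drowsyhog:::pack_bits_msb(bits)
  expect_identical(as.integer(raw[1]), strtoi("b1", 16L))
  expect_identical(drowsyhog:::unpack_bits_msb(raw, 10L), bits)
})
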