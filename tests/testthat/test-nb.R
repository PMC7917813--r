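test_that("m-estimate smoothing and priors match hand arithmetic", {
  # class A: 4 samples, feature 1 set in 3; class B: 6 samples, never set
  X <- rbind(
    matrix(c(1, 1, 1, 0), 4, 1),
    matrix(0, 6, 1)
  )
  y <- c(rep("A", 4), rep("B", 6))
  m <- fit_bernoulli_nb(X, y, m_weight = 2)
  expect_equal(unname(m$p1["A", 1]), (3 + 1) / (4 + 2), tolerance = 1e-15) # 2/3
  expect_equal(unname(m$priors), c(0.4, 0.6), tolerance = 1e-15)
  expect_equal(sum(m$priors), 1, tolerance = 1e-12)

  # never-observed feature in a 5-sample class: 1/(5+2), strictly > 0
  m2 <- fit_bernoulli_nb(rbind(matrix(0, 5, 1), matrix(1, 2, 1)),
                         c(rep("A", 5), rep("B", 2)))
  expect_equal(unname(m2$p1["A", 1]), 1 / 7, tolerance = 1e-15)

  expect_error(fit_bernoulli_nb(matrix(2, 2, 1), c("A", "B")), "binary")
  expect_error(fit_bernoulli_nb(matrix(0, 2, 1), c("A", "B"),
                                m_weight = 0.5), "m_weight")
})

test_that("smoothed Bernoulli parameters are strictly inside (0,1)", {
  set.seed(3)
  X <- matrix(rbinom(40 * 16, 1, 0.05), 40, 16)
  X[, 1] <- 0; X[, 2] <- 1 # degenerate columns
  m <- fit_bernoulli_nb(X, rep(c("a", "b"), each = 20))
  expect_true(all(m$p1 > 0 & m$p1 < 1))
  ll <- log_likelihood(m, X[1, ], "a")
  expect_true(is.finite(ll))
})

test_that("gaussian fit uses population variance with a floor", {
  X <- matrix(c(1, 2, 3, 5, 5, 5), 6, 1)
  y <- c("a", "a", "a", "b", "b", "b")
  m <- fit_gaussian_nb(X, y)
  expect_equal(unname(m$mu["a", 1]), 2, tolerance = 1e-15)
  expect_equal(unname(m$sigma2["a", 1]), 2 / 3, tolerance = 1e-15)
  expect_equal(unname(m$sigma2["b", 1]), 1e-9, tolerance = 1e-20) # floored

  expect_error(fit_gaussian_nb(matrix(1:3, 3, 1), c("a", "a", "b")),
               "two samples")
})

test_that("gaussian fit recovers generating parameters at n = 1000", {
  set.seed(101)
  mu <- c(a = -1.5, b = 2.0)
  sd_ <- c(a = 0.8, b = 1.4)
  X <- matrix(c(rnorm(1000, mu["a"], sd_["a"]),
                rnorm(1000, mu["b"], sd_["b"])), ncol = 1)
  y <- rep(c("a", "b"), each = 1000)
  m <- fit_gaussian_nb(X, y)
  for (cl in c("a", "b")) {
    expect_lt(abs(m$mu[cl, 1] - mu[cl]) / abs(mu[cl]), 0.05)
    expect_lt(abs(sqrt(m$sigma2[cl, 1]) - sd_[cl]) / sd_[cl], 0.05)
  }
})

test_that("log-likelihoods match closed forms and the product space", {
  Xg <- matrix(c(0, 2, 0.1, 1.9), 4, 1)
  mg <- fit_gaussian_nb(Xg, c("a", "b", "a", "b"))
  mg$sigma2[, 1] <- 1; mg$mu["a", 1] <- 0.05
  expect_equal(log_likelihood(mg, 0.05, "a"), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)

  mb <- fit_bernoulli_nb(matrix(c(0, 1), 2, 10), c("a", "b"))
  mb$p1[] <- 0.5
  expect_equal(log_likelihood(mb, rbinom(10, 1, 0.5), "a"), 10 * log(0.5),
               tolerance = 1e-12)

  set.seed(8)
  for (i in 1:20) {
    m <- fit_bernoulli_nb(matrix(rbinom(40, 1, 0.4), 8, 5),
                          rep(c("a", "b"), 4))
    x <- rbinom(5, 1, 0.5)
    ll <- log_likelihood(m, x, "a")
    prod_direct <- prod(ifelse(x == 1, m$p1["a", ], 1 - m$p1["a", ]))
    expect_equal(exp(ll), prod_direct, tolerance = 1e-12)
  }

  expect_error(log_likelihood(mb, c(1, 0), "a"), "mismatch")
})

test_that("MAP prediction normalizes posteriors and breaks ties low", {
  # hand-built symmetric model: equal priors, identical conditionals
  model <- structure(list(
    kind = "bernoulli", classes = c("a", "b"),
    priors = c(a = 0.5, b = 0.5),
    p1 = matrix(0.5, 2, 4, dimnames = list(c("a", "b"), NULL)),
    m_weight = 2, t = 2L, n_features = 4L
  ), class = "nb_model")
  p <- predict_map(model, c(1, 0, 1, 0))
  expect_identical(p$label, "a") # tie -> lowest class index
  expect_equal(rowSums(p$posterior), 1, tolerance = 1e-9)

  # skewed priors, likelihood-equidistant input: MAP follows the
  # prior, ML ties back to the first class
  model$priors <- c(a = 0.1, b = 0.9)
  expect_identical(predict_map(model, c(1, 1, 0, 0))$label, "b")
  expect_identical(predict_ml(model, c(1, 1, 0, 0))$label, "a")
})

test_that("ML equals MAP under equal priors and ignores skewed ones", {
  set.seed(12)
  X <- matrix(rbinom(60 * 12, 1, 0.3), 60, 12)
  y <- rep(c("a", "b"), each = 30)
  m <- fit_bernoulli_nb(X, y)
  Xt <- matrix(rbinom(50 * 12, 1, 0.5), 50, 12)
  expect_identical(predict_map(m, Xt)$label, predict_ml(m, Xt)$label)

  # posterior normalization holds across many random inputs
  p <- predict_map(m, Xt)
  expect_true(all(abs(rowSums(p$posterior) - 1) < 1e-9))
})

test_that("gaussian MAP agrees with an independent reference", {
  skip_if_not_installed("e1071")
  set.seed(33)
  n <- 2000
  X <- rbind(
    cbind(rnorm(n, -1, 0.7), rnorm(n, 0, 1.2)),
    cbind(rnorm(n, 1.2, 0.9), rnorm(n, 1.5, 0.8))
  )
  y <- rep(c("neg", "pos"), each = n)
  m <- fit_gaussian_nb(X, y)
  set.seed(34)
  Xt <- rbind(cbind(rnorm(250, -1, 0.7), rnorm(250, 0, 1.2)),
              cbind(rnorm(250, 1.2, 0.9), rnorm(250, 1.5, 0.8)))
  ours <- predict_map(m, Xt)

  ref <- e1071::naiveBayes(x = as.data.frame(X), y = factor(y))
  ref_lab <- as.character(predict(ref, as.data.frame(Xt)))
  expect_identical(ours$label, ref_lab)

  # posterior agreement against a direct density-product computation
  # from the fitted parameters
  direct <- t(apply(Xt, 1, function(x) {
    s <- vapply(seq_along(m$classes), function(j) {
      m$priors[j] * prod(dnorm(x, m$mu[j, ], sqrt(m$sigma2[j, ])))
    }, numeric(1))
    s / sum(s)
  }))
  expect_equal(unname(ours$posterior), unname(direct), tolerance = 1e-9)
})

test_that("well-separated gaussian classes are classified near-perfectly", {
  set.seed(55)
  n <- 1000
  X <- rbind(cbind(rnorm(n, -2, 0.5), rnorm(n, -2, 0.5)),
             cbind(rnorm(n, 2, 0.5), rnorm(n, 2, 0.5)))
  y <- rep(c("a", "b"), each = n)
  m <- fit_gaussian_nb(X, y)
  acc <- mean(predict_map(m, X)$label == y)
  expect_gte(acc, 0.99)
})

test_that("model files round-trip with identical predictions", {
  set.seed(71)
  X <- matrix(rbinom(30 * 20, 1, 0.4), 30, 20)
  y <- rep(c("closed", "open"), 15)
  m <- fit_bernoulli_nb(X, y)
  path <- withr::local_tempfile(fileext = ".nbm")
  save_nb_model(m, path, layout = drowsyhog:::descriptor_layout(
    2L, 2L, 8L, 8L, "bosh"))
  back <- read_nb_model(path)
  Xt <- matrix(rbinom(100 * 20, 1, 0.5), 100, 20)
  p1 <- predict_map(m, Xt); p2 <- predict_map(back, Xt)
  expect_identical(p1$label, p2$label)
  expect_identical(p1$posterior, p2$posterior)
  expect_identical(attr(back, "layout")$scheme, "bosh")

  mg <- fit_gaussian_nb(matrix(rnorm(40), 20, 2), rep(c("a", "b"), 10))
  pg <- withr::local_tempfile()
  save_nb_model(mg, pg)
  backg <- read_nb_model(pg)
  Xg <- matrix(rnorm(60), 30, 2)
  expect_identical(predict_map(mg, Xg)$posterior,
                   predict_map(backg, Xg)$posterior)
})

test_that("fitted models store m*N conditionals and m-1 free priors", {
  set.seed(2)
  X <- matrix(rbinom(60 * 7, 1, 0.5), 60, 7)
  y <- rep(c("a", "b", "c"), each = 20)
  m <- fit_bernoulli_nb(X, y)
  expect_identical(dim(m$p1), c(3L, 7L)) # m classes x N features
  expect_length(m$priors, 3L)            # m-1 free given sum-to-1
  expect_equal(sum(m$priors), 1, tolerance = 1e-12)
})
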