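#' Fit a Bernoulli Naive Bayes model
#'
#' From-scratch Naive Bayes for binary feature vectors (e.g. BOSH
#' descriptors). Class priors are relative class frequencies.
#' Conditional probabilities use the m-estimate:
#' `P(x_i = 1 | class j) = (n_c + m_weight * alpha) / (n + m_weight)`
#' with `alpha = 1/t` and `t = 2` possible feature values, where `n_c`
#' counts samples of class j with the feature set and `n` the class
#' size. With the default `m_weight = 2` this is add-one (Laplace)
#' smoothing; any `m_weight >= 1` keeps every parameter strictly
#' inside `(0, 1)`, so log-likelihoods are always finite.
#'
#' @param X numeric/integer matrix `n_samples x n_features` of 0/1
#'   values (rows are samples).
#' @param y class labels (character or factor), one per row.
#' @param m_weight m-estimate weight, `>= 1`.
#' @return An object of class `nb_model` with fields `kind`
#'   (`"bernoulli"`), `classes`, `priors`, `p1` (class x feature
#'   matrix of `P(x = 1 | class)`), `m_weight`, `t`, `n_features`.
#' @export
fit_bernoulli_nb <- function(X, y, m_weight = 2.0) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) {
    stop("fit_bernoulli_nb: X rows and y length differ", call. = FALSE)
  }
  if (m_weight < 1) {
    stop("fit_bernoulli_nb: m_weight must be >= 1", call. = FALSE)
  }
  if (any(X != 0 & X != 1)) {
    stop("fit_bernoulli_nb: features must be binary 0/1", call. = FALSE)
  }
  classes <- sort(unique(y))
  if (length(classes) < 1L || any(table(y)[classes] < 1L)) {
    stop("fit_bernoulli_nb: every class needs at least one sample",
         call. = FALSE)
  }
  t_vals <- 2L
  alpha <- 1 / t_vals
  p1 <- matrix(0, length(classes), ncol(X),
               dimnames = list(classes, NULL))
  priors <- numeric(length(classes))
  names(priors) <- classes
  for (j in seq_along(classes)) {
    rows <- y == classes[j]
    n <- sum(rows)
    nc <- colSums(X[rows, , drop = FALSE])
    p1[j, ] <- (nc + m_weight * alpha) / (n + m_weight)
    priors[j] <- n / length(y)
  }
  structure(
    list(kind = "bernoulli", classes = classes, priors = priors,
         p1 = p1, m_weight = m_weight, t = t_vals,
         n_features = ncol(X)),
    class = "nb_model"
  )
}

#' Fit a Gaussian Naive Bayes model
#'
#' Continuous-feature Naive Bayes: each feature's class-conditional
#' distribution is Gaussian with per-class per-feature mean and
#' variance estimated by the sample mean and the population variance
#' (denominator `n`), floored at `var_floor` to keep densities
#' well-defined for constant features.
#'
#' @param X numeric matrix `n_samples x n_features`.
#' @param y class labels, one per row; every class needs `>= 2`
#'   samples.
#' @param var_floor minimum allowed variance.
#' @return An `nb_model` with fields `kind` (`"gaussian"`), `classes`,
#'   `priors`, `mu` and `sigma2` (class x feature matrices),
#'   `n_features`.
#' @export
fit_gaussian_nb <- function(X, y, var_floor = 1e-9) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) {
    stop("fit_gaussian_nb: X rows and y length differ", call. = FALSE)
  }
  classes <- sort(unique(y))
  counts <- table(y)[classes]
  if (any(counts < 2L)) {
    stop("fit_gaussian_nb: every class needs at least two samples",
         call. = FALSE)
  }
  mu <- matrix(0, length(classes), ncol(X), dimnames = list(classes, NULL))
  sigma2 <- mu
  priors <- numeric(length(classes))
  names(priors) <- classes
  for (j in seq_along(classes)) {
    rows <- y == classes[j]
    n <- sum(rows)
    Xi <- X[rows, , drop = FALSE]
    mu[j, ] <- colMeans(Xi)
    sigma2[j, ] <- pmax(colMeans(Xi^2) - colMeans(Xi)^2, var_floor)
    priors[j] <- n / length(y)
  }
  structure(
    list(kind = "gaussian", classes = classes, priors = priors,
         mu = mu, sigma2 = sigma2, var_floor = var_floor,
         n_features = ncol(X)),
    class = "nb_model"
  )
}

#' Class-conditional log-likelihood
#'
#' `sum_i log P(x_i | class_j)` under the fitted model's
#' conditional-independence factorization, computed in log space
#' (the equivalent product form underflows at thousands of features).
#' Bernoulli terms are `log p` where `x_i = 1` and `log(1 - p)`
#' otherwise; Gaussian terms are log normal densities.
#'
#' @param model a fitted `nb_model`.
#' @param x a feature vector of length `model$n_features`.
#' @param class_j class label or index.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(model, x, class_j) {
  stopifnot(inherits(model, "nb_model"))
  if (length(x) != model$n_features) {
    stop("log_likelihood: feature count mismatch", call. = FALSE)
  }
  j <- if (is.numeric(class_j)) as.integer(class_j)
       else match(as.character(class_j), model$classes)
  if (is.na(j) || j < 1L || j > length(model$classes)) {
    stop("log_likelihood: unknown class", call. = FALSE)
  }
  if (model$kind == "bernoulli") {
    p <- model$p1[j, ]
    sum(ifelse(x == 1, log(p), log1p(-p)))
  } else {
    mu <- model$mu[j, ]
    s2 <- model$sigma2[j, ]
    sum(-0.5 * log(2 * pi * s2) - (x - mu)^2 / (2 * s2))
  }
}

# Matrix of per-class log-likelihoods for many samples at once
# (rows of X are samples; returns n_samples x n_classes).
loglik_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("predict: feature count mismatch", call. = FALSE)
  }
  nc <- length(model$classes)
  L <- matrix(0, nrow(X), nc, dimnames = list(NULL, model$classes))
  if (model$kind == "bernoulli") {
    for (j in seq_len(nc)) {
      p <- model$p1[j, ]
      # sum over features: x*log(p) + (1-x)*log(1-p)
      L[, j] <- X %*% (log(p) - log1p(-p)) + sum(log1p(-p))
    }
  } else {
    for (j in seq_len(nc)) {
      mu <- model$mu[j, ]
      s2 <- model$sigma2[j, ]
      ctr <- sweep(X, 2L, mu)
      L[, j] <- -0.5 * sum(log(2 * pi * s2)) -
        (ctr^2 %*% (1 / (2 * s2)))
    }
  }
  L
}

nb_predict <- function(model, X, log_priors) {
  L <- loglik_matrix(model, X)
  S <- sweep(L, 2L, log_priors, `+`)
  # log-sum-exp normalization per row
  mx <- apply(S, 1L, max)
  P <- exp(S - mx)
  P <- P / rowSums(P)
  lab_idx <- max.col(S, ties.method = "first") # tie -> lowest class index
  structure(
    list(
      label = model$classes[lab_idx],
      log_scores = S,
      posterior = P,
      classes = model$classes
    ),
    class = "nb_prediction"
  )
}

#' Predict with the MAP decision rule
#'
#' Maximum a posteriori classification: the label maximizes
#' `log prior_j + log likelihood_j`. Ties break to the lowest class
#' index (classes are kept in sorted order). Posteriors are
#' normalized with log-sum-exp.
#'
#' @param model a fitted `nb_model`.
#' @param X a feature vector or an `n_samples x n_features` matrix.
#' @return An `nb_prediction`: list with `label` (character vector),
#'   `log_scores` and `posterior` matrices (columns are classes).
#' @export
predict_map <- function(model, X) {
  stopifnot(inherits(model, "nb_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  nb_predict(model, X, log(model$priors))
}

#' Predict with the ML decision rule
#'
#' Maximum-likelihood classification: as [predict_map()] but with a
#' uniform prior, so only the likelihood drives the decision.
#'
#' @inheritParams predict_map
#' @return An `nb_prediction`.
#' @export
predict_ml <- function(model, X) {
  stopifnot(inherits(model, "nb_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  nc <- length(model$classes)
  nb_predict(model, X, rep(log(1 / nc), nc))
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Naive Bayes model (%s), %d classes, %d features\n",
              x$kind, length(x$classes), x$n_features))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  priors: ", paste(sprintf("%.4f", x$priors), collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a Naive Bayes model
#'
#' Plain-text model container: a header (kind, classes, feature
#' count, smoothing settings, descriptor layout if any) followed by
#' full-precision parameter tables, one class per line. Round-trips
#' bit-exactly through `%.17g` formatting.
#'
#' @param model a fitted `nb_model`.
#' @param path destination / source file path.
#' @param layout optional descriptor layout list to embed so
#'   prediction can verify feature-geometry compatibility.
#' @return `save_nb_model`: `path` invisibly; `read_nb_model`: the
#'   `nb_model`.
#' @export
save_nb_model <- function(model, path, layout = NULL) {
  stopifnot(inherits(model, "nb_model"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("drowsyhog-nb 1")
  wl("kind %s", model$kind)
  wl("classes %s", paste(model$classes, collapse = " "))
  wl("n_features %d", model$n_features)
  if (model$kind == "bernoulli") {
    wl("m_weight %.17g", model$m_weight)
    wl("t %d", model$t)
  } else {
    wl("var_floor %.17g", model$var_floor)
  }
  if (!is.null(layout)) {
    wl("layout %d %d %d %d %s", layout$patch_w, layout$patch_h,
       layout$cell_size, layout$m, layout$scheme)
  }
  wl("priors %s", paste(sprintf("%.17g", model$priors), collapse = " "))
  if (model$kind == "bernoulli") {
    for (j in seq_along(model$classes)) {
      wl("p1 %s %s", model$classes[j],
         paste(sprintf("%.17g", model$p1[j, ]), collapse = " "))
    }
  } else {
    for (j in seq_along(model$classes)) {
      wl("mu %s %s", model$classes[j],
         paste(sprintf("%.17g", model$mu[j, ]), collapse = " "))
      wl("sigma2 %s %s", model$classes[j],
         paste(sprintf("%.17g", model$sigma2[j, ]), collapse = " "))
    }
  }
  invisible(path)
}

#' @rdname save_nb_model
#' @export
read_nb_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "drowsyhog-nb ")) {
    stop("read_nb_model: not a drowsyhog model file", call. = FALSE)
  }
  fields <- list()
  layout <- NULL
  tabs <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    key <- parts[1]
    if (key %in% c("p1", "mu", "sigma2")) {
      cls <- parts[2]
      tabs[[key]][[cls]] <- as.numeric(parts[-(1:2)])
    } else if (key == "layout") {
      layout <- list(
        patch_w = as.integer(parts[2]), patch_h = as.integer(parts[3]),
        cell_size = as.integer(parts[4]), m = as.integer(parts[5]),
        scheme = parts[6]
      )
    } else {
      fields[[key]] <- parts[-1]
    }
  }
  classes <- fields$classes
  kind <- fields$kind
  priors <- as.numeric(fields$priors)
  names(priors) <- classes
  model <- if (kind == "bernoulli") {
    structure(list(
      kind = "bernoulli", classes = classes, priors = priors,
      p1 = do.call(rbind, tabs$p1[classes]),
      m_weight = as.numeric(fields$m_weight),
      t = as.integer(fields$t),
      n_features = as.integer(fields$n_features)
    ), class = "nb_model")
  } else {
    structure(list(
      kind = "gaussian", classes = classes, priors = priors,
      mu = do.call(rbind, tabs$mu[classes]),
      sigma2 = do.call(rbind, tabs$sigma2[classes]),
      var_floor = as.numeric(fields$var_floor),
      n_features = as.integer(fields$n_features)
    ), class = "nb_model")
  }
  attr(model, "layout") <- layout
  model
}
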