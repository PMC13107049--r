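#' Fit a class-conditional Gaussian mixture classifier
#'
#' Fits one multivariate Gaussian per labeled population by supervised
#' moment matching — no expectation-maximization is involved — and
#' concatenates the components into a mixture used for classification.
#' For population `k`, `mu_k` is the class sample mean and `Sigma_k` the
#' class sample covariance plus `regularization * I`; class priors are
#' uniform by default, so posterior membership reduces to the normalized
#' class densities `P(k | x) = N(x | mu_k, Sigma_k) / sum_j N(x | mu_j,
#' Sigma_j)`.
#'
#' The intended feature space is the pair of spherical angles produced
#' by [spherical_features()], but any numeric features work.
#'
#' @param formula model formula, e.g.
#'   `population ~ angle_cvsg_deg + angle_rvscg_deg`; the response is
#'   the population label, the right-hand side lists feature columns.
#' @param data data.frame holding labels and features.
#' @param regularization nonnegative ridge added to each class
#'   covariance diagonal; the default `1e-6` keeps degenerate
#'   (zero-variance) classes invertible.
#' @param weights optional class prior probabilities (named by label);
#'   default uniform.
#' @return An object of class `fpmix` with components `labels`, `means`
#'   (K x d matrix), `covariances` (list of d x d matrices), `weights`,
#'   `feature_names`, `n_per_class`, `regularization` and `call`.
#'   Supports `print`, `summary`, `coef`, `predict`, `plot` and
#'   `simulate`.
#' @examples
#' cfg <- generator_config(seed = 1, n_cells_per_population = 200)
#' tab <- simulate_intensity_table(tag_library()[1:5, ], cfg)
#' tab <- spherical_features(normalize_global_median(tab))
#' fit <- fpmix(population ~ angle_cvsg_deg + angle_rvscg_deg, tab)
#' pred <- predict(fit, tab)
#' mean(pred$class == tab$population)
#' @export
fpmix <- function(formula, data, regularization = 1e-6, weights = NULL) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            regularization >= 0)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  labels_raw <- mf[[1L]]
  X <- as.matrix(mf[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("features must be numeric")
  lab <- factor(labels_raw)
  labels <- levels(lab)
  K <- length(labels)
  d <- ncol(X)
  if (K < 2L) stop("at least two populations are required")
  means <- matrix(NA_real_, K, d, dimnames = list(labels, colnames(X)))
  covs <- vector("list", K)
  names(covs) <- labels
  n_per <- integer(K)
  for (k in seq_len(K)) {
    Xi <- X[lab == labels[k], , drop = FALSE]
    n_per[k] <- nrow(Xi)
    if (n_per[k] < 1L) stop("empty class: ", labels[k])
    means[k, ] <- colMeans(Xi)
    S <- if (n_per[k] > 1L) stats::cov(Xi) else matrix(0, d, d)
    S <- S + diag(regularization, d)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("covariance of class ", labels[k],
           " is singular after regularization")
    dimnames(S) <- list(colnames(X), colnames(X))
    covs[[k]] <- S
  }
  w <- if (is.null(weights)) rep(1 / K, K) else {
    stopifnot(length(weights) == K, all(weights >= 0), sum(weights) > 0)
    if (!is.null(names(weights))) weights <- weights[labels]
    weights / sum(weights)
  }
  structure(list(labels = labels, means = means, covariances = covs,
                 weights = setNames(w, labels),
                 feature_names = colnames(X),
                 n_per_class = setNames(n_per, labels),
                 regularization = regularization,
                 formula = formula, call = match.call()),
            class = "fpmix")
}

# log N(x | mu, Sigma) for all rows of X, via the Cholesky factor
log_dmvnorm <- function(X, mu, Sigma) {
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

#' Posterior membership probabilities and label predictions
#'
#' Evaluates the class-conditional densities in log space (with
#' max-subtraction before exponentiation, so cells hundreds of standard
#' deviations from every mean still normalize cleanly), combines them
#' with the class priors, and normalizes to posterior membership
#' probabilities. The predicted label is the posterior argmax; exact
#' ties are broken toward the lowest class index and counted in
#' attribute `"n_ties"`. Rows with non-finite features are flagged
#' (`NA` prediction, `NA` posterior row) and counted in attribute
#' `"n_excluded"`, never silently dropped.
#'
#' @param object a fitted [fpmix()] model.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return A list with components `class` (factor of predicted labels),
#'   `posterior` (cells x classes matrix, rows summing to 1) and
#'   `max_posterior` (the per-cell membership probability of the
#'   predicted label).
#' @export
predict.fpmix <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  ok <- apply(is.finite(X), 1L, all)
  K <- length(object$labels)
  logp <- matrix(NA_real_, nrow(X), K,
                 dimnames = list(NULL, object$labels))
  if (any(ok)) {
    Xo <- X[ok, , drop = FALSE]
    for (k in seq_len(K))
      logp[ok, k] <- log_dmvnorm(Xo, object$means[k, ],
                                 object$covariances[[k]]) +
        log(object$weights[k])
  }
  post <- matrix(NA_real_, nrow(X), K,
                 dimnames = list(rownames(newdata), object$labels))
  idx <- rep(NA_integer_, nrow(X))
  n_ties <- 0L
  if (any(ok)) {
    lp <- logp[ok, , drop = FALSE]
    m <- apply(lp, 1L, max)
    e <- exp(lp - m)            # vector m recycles row-wise
    post[ok, ] <- e / rowSums(e)
    idx[ok] <- max.col(post[ok, , drop = FALSE], ties.method = "first")
    n_ties <- sum(apply(post[ok, , drop = FALSE], 1L,
                        function(p) sum(p == max(p)) > 1L))
  }
  out <- list(class = factor(object$labels[idx], levels = object$labels),
              posterior = post,
              max_posterior = post[cbind(seq_len(nrow(X)), idx)])
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "n_ties") <- n_ties
  out
}

#' @export
print.fpmix <- function(x, ...) {
  cat("Class-conditional Gaussian mixture classifier\n")
  cat(sprintf("  %d populations, %d features (%s)\n", length(x$labels),
              length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  %d training cells, covariance ridge %g\n",
              sum(x$n_per_class), x$regularization))
  invisible(x)
}

#' @export
summary.fpmix <- function(object, ...) {
  structure(list(model = object), class = "summary.fpmix")
}

#' @export
print.summary.fpmix <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nClass means:\n")
  print(round(m$means, 3))
  cat("\nCells per class:\n")
  print(m$n_per_class)
  invisible(x)
}

#' @export
coef.fpmix <- function(object, ...) object$means

#' Plot class means and covariance ellipses
#'
#' Draws the fitted class means in the first two feature dimensions with
#' the `level` probability ellipse of each class covariance.
#'
#' @param x a fitted [fpmix()] model.
#' @param level ellipse coverage probability.
#' @param ... passed to [plot()].
#' @export
plot.fpmix <- function(x, level = 0.95, ...) {
  if (length(x$feature_names) < 2L)
    stop("plotting requires at least two features")
  mu <- x$means[, 1:2, drop = FALSE]
  rad <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = 100)
  circ <- rbind(cos(theta), sin(theta)) * rad
  ell <- lapply(seq_along(x$labels), function(k) {
    R <- chol(x$covariances[[k]][1:2, 1:2])
    t(t(R) %*% circ + mu[k, ])
  })
  xl <- range(vapply(ell, function(e) range(e[, 1]), numeric(2)))
  yl <- range(vapply(ell, function(e) range(e[, 2]), numeric(2)))
  plot(mu, xlim = xl, ylim = yl, pch = 3,
       xlab = x$feature_names[1], ylab = x$feature_names[2], ...)
  for (k in seq_along(ell)) lines(ell[[k]], col = k)
  text(mu, labels = x$labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' Simulate cells from a fitted classifier
#'
#' Draws feature vectors from the fitted class-conditional Gaussians,
#' `nsim` cells per class.
#'
#' @param object a fitted [fpmix()] model.
#' @param nsim cells per class.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with the label column and feature columns.
#' @export
simulate.fpmix <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    d <- length(object$feature_names)
    out <- lapply(seq_along(object$labels), function(k) {
      R <- chol(object$covariances[[k]])
      Z <- matrix(rnorm(nsim * d), nsim, d)
      X <- Z %*% R + matrix(object$means[k, ], nsim, d, byrow = TRUE)
      colnames(X) <- object$feature_names
      cbind(data.frame(population = object$labels[k],
                       stringsAsFactors = FALSE), as.data.frame(X))
    })
    do.call(rbind, out)
  })
}
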