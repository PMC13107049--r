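#' Pairwise discriminability of two populations
#'
#' Pools the cells of two populations (optionally balanced by
#' subsampling the larger to the size of the smaller), fits an
#' unsupervised two-component Gaussian mixture by
#' expectation-maximization (no training labels are used), and scores
#' the fraction of cells correctly grouped under the better of the two
#' possible cluster-to-population assignments. Identical populations
#' therefore score about 0.5 (chance under the best-assignment rule)
#' and well-separated populations approach 1.
#'
#' @param cells_a,cells_b numeric feature matrices (one row per cell).
#' @param seed integer seed (drives the balancing subsample).
#' @param balance subsample the larger population to the smaller?
#' @param min_cells minimum cells required in each population.
#' @return Accuracy in \[0.5-ish, 1\], with the pooled cell count as
#'   attribute `"n"`.
#' @export
pairwise_accuracy <- function(cells_a, cells_b, seed = NULL,
                              balance = TRUE, min_cells = 20) {
  A <- as.matrix(cells_a); B <- as.matrix(cells_b)
  if (nrow(A) < min_cells || nrow(B) < min_cells)
    stop("each population needs at least ", min_cells, " cells")
  with_seed(seed, {
    if (balance) {
      n <- min(nrow(A), nrow(B))
      if (nrow(A) > n) A <- A[sample.int(nrow(A), n), , drop = FALSE]
      if (nrow(B) > n) B <- B[sample.int(nrow(B), n), , drop = FALSE]
    }
    X <- rbind(A, B)
    truth <- rep(1:2, c(nrow(A), nrow(B)))
    # canonical row order makes the fit independent of argument order
    ord <- do.call(order, as.data.frame(X))
    cls <- fit_two_component(X[ord, , drop = FALSE])[order(ord)]
    acc <- max(mean(cls == truth), mean((3L - cls) == truth))
    structure(acc, n = nrow(X))
  })
}

# Two-component EM fit; tries progressively simpler covariance
# parameterizations if the richest one fails to converge.
fit_two_component <- function(X) {
  for (mod in c("VVV", "EEE", "EII")) {
    fit <- tryCatch(
      Mclust(X, G = 2, modelNames = mod, verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$classification))
      return(fit$classification)
  }
  stop("two-component mixture failed to converge")
}

#' Pairwise discriminability matrix over a population panel
#'
#' Applies [pairwise_accuracy()] to every unordered pair of populations
#' in a labeled feature table. Each pair is computed once and mirrored,
#' so the matrix is exactly symmetric; the diagonal is `NA` (a
#' population cannot be discriminated from itself).
#'
#' @param features numeric feature matrix or data.frame.
#' @param labels population label per row.
#' @param seed integer seed; each pair receives a deterministic sub-seed
#'   so the full matrix is reproducible.
#' @param balance,min_cells passed to [pairwise_accuracy()].
#' @param verbose print progress every 200 pairs?
#' @return A `pairwise_matrix`: symmetric numeric matrix with population
#'   ids as dimnames and per-pair pooled cell counts as attribute
#'   `"n_cells"`.
#' @export
pairwise_matrix <- function(features, labels, seed = NULL, balance = TRUE,
                            min_cells = 20, verbose = FALSE) {
  X <- as.matrix(features)
  lab <- as.character(labels)
  stopifnot(nrow(X) == length(lab))
  ids <- sort(unique(lab))
  if (length(ids) < 2L) stop("at least two populations are required")
  K <- length(ids)
  M <- matrix(NA_real_, K, K, dimnames = list(ids, ids))
  Ncell <- matrix(NA_integer_, K, K, dimnames = list(ids, ids))
  rows <- split(seq_len(nrow(X)), lab)
  pair_no <- 0L
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    pair_no <- pair_no + 1L
    sub_seed <- if (is.null(seed)) NULL else (seed + pair_no) %% .Machine$integer.max
    acc <- pairwise_accuracy(X[rows[[ids[i]]], , drop = FALSE],
                             X[rows[[ids[j]]], , drop = FALSE],
                             seed = sub_seed, balance = balance,
                             min_cells = min_cells)
    M[i, j] <- M[j, i] <- as.numeric(acc)
    Ncell[i, j] <- Ncell[j, i] <- attr(acc, "n")
    if (verbose && pair_no %% 200L == 0L)
      message("pairwise_matrix: ", pair_no, " pairs done")
  }
  structure(M, n_cells = Ncell, class = c("pairwise_matrix", "matrix"))
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise discriminability matrix: %d populations\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Minimum pairwise discriminability within a subset
#'
#' The worst pairwise accuracy among all unordered pairs of the given
#' populations — the quantity a panel search maximizes, since it
#' reflects a subset's ability to distinguish its most similar pair.
#' Subsets of fewer than two populations return the vacuous minimum 1
#' (with a warning).
#'
#' @param matrix a [pairwise_matrix()] (any symmetric accuracy matrix
#'   with dimnames works).
#' @param subset character vector of population ids (or integer
#'   indices).
#' @return The minimum accuracy over pairs within the subset.
#' @export
min_pairwise <- function(matrix, subset) {
  idx <- if (is.character(subset)) match(subset, rownames(matrix)) else subset
  if (anyNA(idx)) stop("subset ids missing from the matrix")
  if (length(idx) < 2L) {
    warning("subset smaller than 2: returning the vacuous minimum 1")
    return(1)
  }
  sub <- matrix[idx, idx]
  min(sub[upper.tri(sub)])
}

#' Max–min panel search by random sampling
#'
#' Draws `n_draws` uniform random `k`-subsets of the populations
#' (without replacement within a draw; draws are independent, so
#' repeats across draws are possible and harmless) and returns the
#' subset with the largest [min_pairwise()] value. Ties keep the
#' first subset found. This is the sampling strategy used to pick a
#' maximally discriminable panel when exhaustive enumeration of
#' `C(n, k)` subsets is out of reach.
#'
#' @param matrix a [pairwise_matrix()].
#' @param k subset size, between 2 and the number of populations.
#' @param n_draws number of random subsets to evaluate.
#' @param seed integer seed; results are bit-reproducible.
#' @return A list of class `panel_search`: `subset` (population ids),
#'   `value` (achieved max–min accuracy), `k`, `n_draws`, `seed`,
#'   `method = "random"`.
#' @export
maxmin_search <- function(matrix, k, n_draws = 1e5, seed = NULL) {
  n <- nrow(matrix)
  if (k < 2L || k > n) stop("k must lie in [2, number of populations]")
  stopifnot(n_draws >= 1)
  with_seed(seed, {
    best_val <- -Inf
    best_sub <- NULL
    for (b in seq_len(n_draws)) {
      idx <- sample.int(n, k)
      sub <- matrix[idx, idx]
      v <- min(sub[upper.tri(sub)])
      if (v > best_val) { best_val <- v; best_sub <- sort(idx) }
    }
    structure(list(subset = rownames(matrix)[best_sub], value = best_val,
                   k = as.integer(k), n_draws = as.integer(n_draws),
                   seed = seed, method = "random"),
              class = "panel_search")
  })
}

#' Exact max–min panel search by exhaustive enumeration
#'
#' Enumerates every `k`-subset and returns the exact optimum. Intended
#' as the brute-force reference for [maxmin_search()] on instances small
#' enough to enumerate; refuses when `C(n, k)` exceeds `cap`.
#'
#' @param matrix a [pairwise_matrix()].
#' @param k subset size.
#' @param cap maximum number of subsets to enumerate.
#' @return A `panel_search` list with `method = "exhaustive"`.
#' @export
maxmin_exhaustive <- function(matrix, k, cap = 1e6) {
  n <- nrow(matrix)
  if (k < 2L || k > n) stop("k must lie in [2, number of populations]")
  n_sub <- choose(n, k)
  if (n_sub > cap)
    stop(sprintf("C(%d, %d) = %.3g exceeds the enumeration cap %g",
                 n, k, n_sub, cap))
  best_val <- -Inf
  best_sub <- NULL
  combs <- combn(n, k)
  for (b in seq_len(ncol(combs))) {
    idx <- combs[, b]
    sub <- matrix[idx, idx]
    v <- min(sub[upper.tri(sub)])
    if (v > best_val) { best_val <- v; best_sub <- idx }
  }
  structure(list(subset = rownames(matrix)[best_sub], value = best_val,
                 k = as.integer(k), n_draws = as.integer(n_sub),
                 seed = NULL, method = "exhaustive"),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("Max-min panel search (%s): k = %d, %d subsets evaluated\n",
              x$method, x$k, x$n_draws))
  cat(sprintf("  achieved minimum pairwise accuracy: %.4f\n", x$value))
  cat("  panel:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}
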