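# Shared fixtures, all generated in code.

# noiseless generator: every cell of a tag lands exactly on its expected
# channel vector
noiseless_config <- function(amp = 2, base = 1, ref = 1) {
  generator_config(amp = amp, base_brightness = base, sigma_expr = 0,
                   sigma_chan = 0, bg_mean = 0, bg_sd = 0,
                   ref_brightness = ref)
}

# single-channel ladder panel: copy numbers 1, 2, 4, 8 on the C channel
ladder_panel <- function(copies = c(1, 2, 4, 8)) {
  data.frame(tag_id = sprintf("C%dG0R0", copies),
             c_C = copies, c_G = 0, c_R = 0)
}

# symmetric accuracy matrix with given off-diagonal entries (row-major
# upper triangle), NA diagonal
make_matrix <- function(ids, upper) {
  K <- length(ids)
  M <- matrix(NA_real_, K, K, dimnames = list(ids, ids))
  M[upper.tri(M)] <- upper
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  structure(M, class = c("pairwise_matrix", "matrix"))
}

# random symmetric accuracy matrix in [0.5, 1]
random_matrix <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("p", seq_len(n))
  make_matrix(ids, runif(n * (n - 1) / 2, 0.5, 1))
}

# independent naive posterior evaluator: plain density formula, no
# log-space tricks
naive_posterior <- function(model, X) {
  dens <- sapply(seq_along(model$labels), function(k) {
    S <- model$covariances[[k]]
    mu <- model$means[k, ]
    apply(X, 1, function(x) {
      d <- length(x)
      exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu)) /
        sqrt((2 * pi)^d * det(S))
    }) * model$weights[k]
  })
  dens / rowSums(dens)
}

# brute-force nearest-neighbor distances, O(n^2) double loop
brute_nn <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2)
    out[i] <- min(d)
  }
  out
}

# brute-force heterotypic nearest-neighbor label counts
brute_het_counts <- function(pp, target) {
  others <- sort(unique(pp$labels[pp$labels != target]))
  counts <- setNames(integer(length(others)), others)
  for (i in which(pp$labels == target)) {
    j_all <- which(pp$labels != target)
    d <- sqrt((pp$x[i] - pp$x[j_all])^2 + (pp$y[i] - pp$y[j_all])^2)
    lab <- pp$labels[j_all[which.min(d)]]
    counts[lab] <- counts[lab] + 1L
  }
  counts
}
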