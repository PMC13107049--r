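two_gaussians <- function(n, sep, seed) {
  set.seed(seed)
  list(a = cbind(rnorm(n), rnorm(n)),
       b = cbind(rnorm(n, sep), rnorm(n)))
}

test_that("pairwise accuracy hits chance for identical populations and
          certainty for separated ones", {
  g <- two_gaussians(300, 0, 1)
  acc_same <- pairwise_accuracy(g$a, g$b, seed = 2)
  # chance floor: within 3 binomial SDs of 0.5
  expect_lt(abs(acc_same - 0.5), 3 * sqrt(0.25 / 600))

  g2 <- two_gaussians(300, 20, 3)  # 20 pooled SDs apart
  expect_gt(pairwise_accuracy(g2$a, g2$b, seed = 4), 0.999)

  # symmetry contract
  expect_equal(as.numeric(pairwise_accuracy(g2$a, g2$b, seed = 5)),
               as.numeric(pairwise_accuracy(g2$b, g2$a, seed = 5)))
  expect_error(pairwise_accuracy(g2$a[1:5, ], g2$b), "at least")
})

test_that("balancing subsamples the larger population", {
  g <- two_gaussians(400, 10, 6)
  acc <- pairwise_accuracy(g$a[1:50, ], g$b, seed = 7)
  expect_equal(attr(acc, "n"), 100L)
  acc_nb <- pairwise_accuracy(g$a[1:50, ], g$b, seed = 7, balance = FALSE)
  expect_equal(attr(acc_nb, "n"), 450L)
})

test_that("the pairwise matrix is symmetric with sensible extremes", {
  set.seed(8)
  X <- rbind(cbind(rnorm(80), rnorm(80)),
             cbind(rnorm(80, 15), rnorm(80)),
             cbind(rnorm(80), rnorm(80, 15)))
  lab <- rep(c("p1", "p2", "p3"), each = 80)
  M <- pairwise_matrix(X, lab, seed = 9, min_cells = 20)
  expect_true(isSymmetric(unclass(M)))
  expect_true(all(is.na(diag(M))))
  expect_true(all(M[upper.tri(M)] > 0.99))

  Xsame <- rbind(cbind(rnorm(120), rnorm(120)),
                 cbind(rnorm(120), rnorm(120)))
  Msame <- pairwise_matrix(Xsame, rep(c("q1", "q2"), each = 120), seed = 10)
  expect_lt(abs(Msame["q1", "q2"] - 0.5), 0.1)
})

test_that("min_pairwise reduces correctly over subsets", {
  M <- make_matrix(c("a", "b", "c", "d"),
                   c(0.9, 0.8, 0.7, 0.95, 0.6, 0.85))
  # upper triangle fills column-wise: ab=.9 ac=.8 bc=.7 ad=.95 bd=.6 cd=.85
  expect_equal(min_pairwise(M, c("a", "b", "c", "d")),
               min(M[upper.tri(M)]))
  expect_equal(min_pairwise(M, c("a", "d")), M["a", "d"])
  expect_equal(min_pairwise(M, c("a", "c", "d")),
               min(M["a", "c"], M["a", "d"], M["c", "d"]))
  expect_warning(v <- min_pairwise(M, "a"), "vacuous")
  expect_equal(v, 1)
  expect_error(min_pairwise(M, c("a", "zz")), "missing")
})

test_that("random max-min search agrees with exhaustive enumeration", {
  M <- random_matrix(8, seed = 12)
  for (k in c(2, 3, 4)) {
    ex <- maxmin_exhaustive(M, k)
    rs <- maxmin_search(M, k, n_draws = 5000, seed = 13)
    expect_equal(rs$value, ex$value)
    expect_equal(sort(rs$subset), sort(ex$subset))
    # reported value always equals the recomputed subset minimum
    expect_equal(rs$value, min_pairwise(M, rs$subset))
  }
  # k = 2 with ample draws returns the matrix maximum
  expect_equal(maxmin_search(M, 2, 5000, seed = 14)$value,
               max(M, na.rm = TRUE))
  # bit-exact reproducibility
  r1 <- maxmin_search(M, 4, 2000, seed = 15)
  r2 <- maxmin_search(M, 4, 2000, seed = 15)
  expect_identical(r1, r2)
  expect_error(maxmin_search(M, 1, 10), "k must lie")
})

test_that("exhaustive search recovers a planted optimal triple", {
  # pairs within {a, b, c} get accuracy 0.99; every other pair is lower
  set.seed(16)
  M <- make_matrix(letters[1:6],
                   pmin(runif(15, 0.5, 1), 0.9))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c")))
    M[p[1], p[2]] <- M[p[2], p[1]] <- 0.99
  ex <- maxmin_exhaustive(M, 3)
  expect_equal(sort(ex$subset), c("a", "b", "c"))
  expect_equal(ex$value, 0.99)
})

test_that("exhaustive dominates random search and the curve is monotone", {
  for (s in 21:23) {
    M <- random_matrix(9, seed = s)
    vals <- vapply(2:6, function(k) maxmin_exhaustive(M, k)$value,
                   numeric(1))
    expect_true(all(diff(vals) <= 0))  # non-increasing in subset size
    for (k in c(3, 5)) {
      expect_gte(maxmin_exhaustive(M, k)$value,
                 maxmin_search(M, k, 200, seed = s + 1)$value)
    }
  }
  M <- random_matrix(30, seed = 30)
  expect_error(maxmin_exhaustive(M, 15, cap = 1e4), "cap")
})

test_that("pairwise matrices round-trip through CSV", {
  M <- random_matrix(5, seed = 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_matrix(M, path)
  M2 <- read_pairwise_matrix(path)
  expect_equal(unclass(M2), unclass(M)[rownames(M2), colnames(M2)],
               tolerance = 1e-12)
})
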