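make_toy_fit <- function(seed = 1, n = 200, sep = 6) {
  set.seed(seed)
  df <- data.frame(
    population = rep(c("a", "b", "c"), each = n),
    f1 = rnorm(3 * n, rep(c(0, sep, 0), each = n)),
    f2 = rnorm(3 * n, rep(c(0, 0, sep), each = n)))
  fpmix(population ~ f1 + f2, df)
}

test_that("fitting is supervised moment matching with uniform priors", {
  # degenerate class: zero-variance features collapse onto the ridge
  df <- data.frame(population = rep(c("a", "b"), each = 5),
                   f1 = c(rep(45, 5), rnorm(5, 10)),
                   f2 = c(rep(45, 5), rnorm(5, 10)))
  fit <- fpmix(population ~ f1 + f2, df, regularization = 1e-6)
  expect_equal(unname(fit$means["a", ]), c(45, 45))
  expect_equal(unname(fit$covariances[["a"]]), diag(1e-6, 2))
  expect_equal(unname(fit$weights), c(0.5, 0.5))

  # recovery of generator parameters on well-separated classes
  set.seed(2)
  n <- 10000
  df2 <- data.frame(population = rep(c("a", "b"), each = n),
                    f1 = c(rnorm(n, 0, 1), rnorm(n, 20, 2)))
  fit2 <- fpmix(population ~ f1, df2)
  expect_equal(unname(fit2$means[, 1]), c(0, 20), tolerance = 0.05)
  expect_equal(sqrt(fit2$covariances[["b"]][1, 1]), 2, tolerance = 0.05)
})

test_that("posteriors match symmetry and near-certainty limits", {
  df <- data.frame(population = rep(c("a", "b"), each = 50),
                   f1 = rep(c(0, 10), each = 50))
  fit <- fpmix(population ~ f1, df, regularization = 1)  # sd 1 each
  p <- predict(fit, data.frame(f1 = 5))
  expect_equal(unname(p$posterior[1, ]), c(0.5, 0.5))
  p0 <- predict(fit, data.frame(f1 = 0))
  expect_gt(p0$posterior[1, "a"], 0.999)
  expect_equal(as.character(p0$class), "a")
})

test_that("log-space posteriors equal the naive density-ratio oracle", {
  fit <- make_toy_fit()
  set.seed(3)
  X <- cbind(f1 = runif(300, -3, 9), f2 = runif(300, -3, 9))
  p <- predict(fit, as.data.frame(X))
  expect_lt(max(abs(p$posterior - naive_posterior(fit, X))), 1e-9)
})

test_that("posteriors normalize and survive extreme inputs", {
  fit <- make_toy_fit()
  set.seed(4)
  X <- data.frame(f1 = runif(10000, -50, 50), f2 = runif(10000, -50, 50))
  p <- predict(fit, X)
  expect_lt(max(abs(rowSums(p$posterior) - 1)), 1e-9)
  expect_equal(p$max_posterior,
               p$posterior[cbind(seq_len(nrow(X)),
                                 match(p$class, fit$labels))])
  # ~1000 standard deviations away: still finite and normalized
  pfar <- predict(fit, data.frame(f1 = 1000, f2 = -1000))
  expect_equal(sum(pfar$posterior), 1)
  expect_true(all(is.finite(pfar$posterior)))
})

test_that("non-finite feature rows are flagged, not dropped", {
  fit <- make_toy_fit()
  X <- data.frame(f1 = c(0, NA, 6), f2 = c(0, 1, 0))
  p <- predict(fit, X)
  expect_equal(attr(p, "n_excluded"), 1L)
  expect_true(is.na(p$class[2]))
  expect_equal(as.character(p$class[c(1, 3)]), c("a", "b"))
  expect_equal(nrow(p$posterior), 3L)
})

test_that("misclassifications concentrate between adjacent copy numbers", {
  cfg <- generator_config(seed = 21, n_cells_per_population = 2000)
  tab <- simulate_intensity_table(ladder_panel(), cfg)
  tab <- subtract_background(tab, c(ch_C = cfg$bg_mean,
                                    ch_ref = cfg$bg_mean))
  tab$angle <- polar_angle(tab$ch_C, tab$ch_ref)
  sp <- stratified_split(tab, 0.8, seed = 22)
  fit <- fpmix(population ~ angle, sp$train)
  pred <- predict(fit, sp$test)
  level <- function(id) log2(parse_tag_id(as.character(id))$c_C) + 1
  dlev <- abs(level(pred$class) - level(sp$test$population))
  expect_gt(mean(dlev == 1), mean(dlev > 1))
  expect_gt(mean(dlev == 0), 0.9)
})

test_that("high-posterior calls are empirically more accurate", {
  cfg <- generator_config(seed = 31, n_cells_per_population = 400)
  panel <- tag_library()[seq(1, 96, by = 5), ]
  tab <- spherical_features(normalize_global_median(
    subtract_background(simulate_intensity_table(panel, cfg),
                        c(ch_C = 5, ch_G = 5, ch_R = 5))))
  sp <- stratified_split(tab[tab$valid, ], 0.8, seed = 32)
  fit <- fpmix(population ~ angle_cvsg_deg + angle_rvscg_deg, sp$train)
  pred <- predict(fit, sp$test)
  correct <- pred$class == sp$test$population
  hi <- pred$max_posterior >= 0.95
  expect_gt(sum(hi), 50)
  expect_gt(sum(!hi), 50)
  expect_gt(mean(correct[hi]), mean(correct[!hi]))
})

test_that("model JSON serialization round-trips predictions exactly", {
  fit <- make_toy_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_fpmix(fit, path)
  fit2 <- read_fpmix(path)
  expect_equal(fit2$means, fit$means)
  expect_equal(fit2$covariances, fit$covariances)
  X <- data.frame(f1 = c(0, 3, 6), f2 = c(1, 2, 3))
  expect_equal(predict(fit2, X)$posterior, predict(fit, X)$posterior)
})

test_that("standard S3 methods behave", {
  fit <- make_toy_fit()
  expect_output(print(fit), "Class-conditional")
  expect_output(print(summary(fit)), "Class means")
  expect_equal(coef(fit), fit$means)
  sim <- simulate(fit, nsim = 20, seed = 5)
  expect_equal(nrow(sim), 60L)
  expect_equal(colMeans(sim[sim$population == "b", c("f1", "f2")]),
               fit$means["b", ], tolerance = 1)
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
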