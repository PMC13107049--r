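test_that("nearest-neighbor distances match the all-pairs oracle", {
  pp <- point_pattern(c(0, 5), c(0, 0), c("a", "a"), region_area = 100)
  expect_equal(nn_distances(pp), c(5, 5))

  # unit-spacing lattice: every nearest neighbor is one step away
  g <- expand.grid(x = 1:10, y = 1:10)
  ppl <- point_pattern(g$x, g$y, rep("a", 100), region_area = 100)
  expect_equal(nn_distances(ppl), rep(1, 100))

  set.seed(50)
  x <- runif(200, 0, 50); y <- runif(200, 0, 50)
  ppr <- point_pattern(x, y, rep("a", 200), region_area = 2500)
  expect_equal(nn_distances(ppr), brute_nn(x, y), tolerance = 1e-12)

  # label filtering restricts the neighbor set
  ppm <- point_pattern(c(0, 1, 10), c(0, 0, 0), c("a", "b", "a"), 100)
  expect_equal(nn_distances(ppm, label = "a"), c(10, 10))
  expect_error(nn_distances(ppm, label = "b"), "at least two")
})

test_that("the Clark-Evans index separates the canonical regimes", {
  # coincident points: zero observed distance
  pp0 <- point_pattern(rep(1, 10), rep(2, 10), rep("a", 10),
                       region_area = 100)
  expect_equal(clark_evans(pp0)$R, 0)

  # large square lattice with area = n * spacing^2: R -> 2
  m <- 40
  g <- expand.grid(x = 1:m, y = 1:m)
  ppl <- point_pattern(g$x, g$y, rep("a", m^2), region_area = m^2)
  expect_equal(clark_evans(ppl)$R, 2)

  # CSR with the true area: R near 1
  set.seed(51)
  Rs <- replicate(30, {
    pp <- point_pattern(runif(800), runif(800), rep("a", 800),
                        region_area = 1)
    clark_evans(pp)$R
  })
  expect_equal(mean(Rs), 1, tolerance = 0.03)

  # per-label computation and area fallbacks
  set.seed(52)
  pp <- point_pattern(runif(300, 0, 100), runif(300, 0, 100),
                      sample(c("a", "b"), 300, TRUE), region_area = 1e4)
  r_given <- clark_evans(pp, "a", area_mode = "given")
  r_bb <- clark_evans(pp, "a", area_mode = "bounding_box")
  r_ch <- clark_evans(pp, "a", area_mode = "convex_hull")
  expect_equal(r_given$area, 1e4)
  expect_lt(r_bb$area, 1e4)
  expect_lt(r_ch$area, r_bb$area)
  expect_equal(r_given$R, r_given$mean_observed / r_given$mean_expected)

  pp_na <- point_pattern(runif(50), runif(50), rep("a", 50))
  expect_message(r_fb <- clark_evans(pp_na), "bounding box")
  expect_equal(r_fb$area_mode, "bounding_box")
})

test_that("heterotypic nearest-neighbor counts are exact and conserved", {
  # one target cell: B at distance 1 beats C at distance 2
  pp <- point_pattern(c(0, 1, 2), c(0, 0, 0), c("t", "B", "C"), 100)
  expect_equal(heterotypic_nn_counts(pp, "t"), c(B = 1L, C = 0L))

  # conservation and agreement with the O(n^2) oracle on a crafted set
  set.seed(53)
  pp2 <- point_pattern(runif(50, 0, 10), runif(50, 0, 10),
                       sample(c("t", "u", "v"), 50, TRUE,
                              prob = c(0.4, 0.3, 0.3)),
                       region_area = 100)
  counts <- heterotypic_nn_counts(pp2, "t")
  expect_equal(sum(counts), sum(pp2$labels == "t"))
  expect_equal(counts, brute_het_counts(pp2, "t"))

  pp3 <- point_pattern(c(0, 1), c(0, 0), c("t", "t"), 10)
  expect_error(heterotypic_nn_counts(pp3, "t"), "non-target")
  expect_error(heterotypic_nn_counts(pp2, "zz"), "absent")
})

test_that("adjacency ratios detect attraction and stay near 1 under CSR", {
  ratios_B <- vapply(1:5, function(s) {
    pp <- simulate_point_pattern(c(A = 120, B = 120, C = 120), 800, 800,
                                 mode = "random", seed = 60 + s)
    nn_adjacency_ratio(pp, "A", n_shuffles = 60, seed = 70 + s)$ratio[["B"]]
  }, numeric(1))
  expect_equal(mean(ratios_B), 1, tolerance = 0.1)

  pp_att <- simulate_point_pattern(c(A = 120, B = 120, C = 120), 800, 800,
                                   mode = "attracted",
                                   mode_params = list(pair = c("A", "B"),
                                                      radius = 12,
                                                      prob = 0.8),
                                   seed = 81)
  res <- nn_adjacency_ratio(pp_att, "A", n_shuffles = 100, seed = 82)
  expect_gt(res$ratio[["B"]], 1.2)
  expect_lt(res$p_value[["B"]], 0.05)
  expect_equal(sum(res$observed), 120)
  expect_equal(dim(res$null_counts), c(100L, 2L))

  r1 <- nn_adjacency_ratio(pp_att, "A", n_shuffles = 20, seed = 83)
  r2 <- nn_adjacency_ratio(pp_att, "A", n_shuffles = 20, seed = 83)
  expect_identical(r1, r2)
})

test_that("the permutation null is calibrated under exchangeable labels", {
  # when the observed data are themselves a draw from the null, the
  # empirical p-value should be (discretely) uniform
  ps <- vapply(1:60, function(s) {
    pp <- simulate_point_pattern(c(A = 60, B = 60, C = 60), 500, 500,
                                 mode = "random", seed = 100 + s)
    nn_adjacency_ratio(pp, "A", n_shuffles = 40,
                       seed = 200 + s)$p_value[["B"]]
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.70)
  expect_gt(mean(ps < 0.3), 0.1)   # mass in both tails
  expect_gt(mean(ps > 0.7), 0.1)
})
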