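# fptag

Cell identification from trichromatic split-fluorescent-protein
intensity barcodes.

## The problem

Multiplexed live-cell experiments need many co-cultured populations to
be told apart in one image. Classic multicolor labeling with $n$ on/off
fluorophores caps out at $2^n - 1$ combinations (31 for five colors).
Tandem arrays of split-FP eleventh-strand (FP11) peptides lift that
limit: the *copy number* of the array tunes complemented brightness, so
a triple of repeat counts $(c_C, c_G, c_R)$ for three spectral channels
(CFP2, mNG3Asp, sfCherry3Csp) is an intensity barcode. Over copy-number
levels $\{0,1,2,4,8\}$ with total repeats capped at 12 there are 96
such barcodes.

`fptag` implements the complete desk-side analysis for this labeling
scheme, for anyone with a per-cell intensity table (from segmented
microscopy images or flow cytometry):

* **Tag-library combinatorics** — enumeration under level-set and
  total-repeat constraints, exact panel counts
  ($\binom{96}{20} \approx 2\times10^{20}$).
* **Synthetic data** — a calibrated generator for per-cell intensities
  (sub-linear ~1.7-fold gain per copy-number doubling, log-normal
  expression and channel noise, additive background) and for labeled
  spatial point patterns (random / clustered / attracted).
* **Featurization** — background subtraction, pooled-median
  normalization, and the scale-free spherical angles
  $\theta_{CvsG} = \arctan(G/C)$,
  $\theta_{RvsCG} = \arccos(R/r)$ with
  $r = \sqrt{C^2 + G^2 + R^2}$.
* **Classification** — `fpmix()`, a class-conditional Gaussian mixture
  fitted by supervised moment matching, with posterior membership
  probabilities
  $P(k \mid x) \propto \mathcal N(x \mid \mu_k, \Sigma_k)$ as per-cell
  reliability scores; confusion/accuracy/sensitivity metrics and an
  unsupervised k-means alternative with majority-vote cluster merging.
* **Panel selection** — pairwise discriminability via unsupervised
  two-component mixtures, and max–min subset search (random sampling
  plus an exhaustive oracle).
* **Spatial statistics** — Clark–Evans dispersion index
  $R = \bar d_{\min} / (0.5/\sqrt{\rho})$ and heterotypic
  nearest-neighbor adjacency ratios against a label-permutation null.

## Worked example

Simulate a 19-tag panel, classify held-out cells, and inspect
reliability:

```r
library(fptag)

lib <- tag_library()        # 96 tags over {0,1,2,4,8}, total <= 12
cfg <- generator_config(seed = 1, n_cells_per_population = 400)
panel <- lib[seq(2, 96, by = 5), ]

tab <- simulate_intensity_table(panel, cfg)
tab <- subtract_background(tab, c(ch_C = 5, ch_G = 5, ch_R = 5))
tab <- spherical_features(normalize_global_median(tab))

sp  <- stratified_split(tab[tab$valid, ], 0.8, seed = 2)
fit <- fpmix(population ~ angle_cvsg_deg + angle_rvscg_deg, sp$train)
fit
#> Class-conditional Gaussian mixture classifier
#>   19 populations, 2 features (angle_cvsg_deg, angle_rvscg_deg)
#>   6080 training cells, covariance ridge 1e-06

pred <- predict(fit, sp$test)
mean(pred$class == sp$test$population)   # pooled test accuracy
#> [1] 0.9789474
mean(pred$max_posterior >= 0.95)         # fraction of high-reliability calls
#> [1] 0.9078947
```

About 98% of held-out cells are assigned their true barcode, and 91%
carry a membership probability above 0.95 — the posterior doubles as a
per-cell confidence score for pooled samples.

Panel selection shows *why* selection is needed. Tags that differ only
in the copy number of a single color produce the same channel ratios,
so they collapse in angle space:

```r
panel6 <- lib[c(1, 4, 20, 40, 70, 96), ]
tab6 <- spherical_features(normalize_global_median(
  subtract_background(simulate_intensity_table(panel6,
    generator_config(seed = 1, n_cells_per_population = 200)),
    c(ch_C = 5, ch_G = 5, ch_R = 5))))
M <- pairwise_matrix(tab6[, c("angle_cvsg_deg", "angle_rvscg_deg")],
                     tab6$population, seed = 3)
M
#> Pairwise discriminability matrix: 6 populations
#>        C0G0R1 C0G0R8 C0G8R0 C1G4R1 C4G0R2 C8G4R0
#> C0G0R1     NA   0.52      1      1      1      1
#> C0G0R8   0.52     NA      1      1      1      1
#> ...

maxmin_search(M, k = 4, n_draws = 2000, seed = 4)
#> Max-min panel search (random): k = 4, 2000 subsets evaluated
#>   achieved minimum pairwise accuracy: 1.0000
#>   panel: C0G8R0, C1G4R1, C4G0R2, C8G4R0
```

The two pure-red tags (`C0G0R1` vs `C0G0R8`) sit at chance (0.52), and
the max–min search returns a 4-tag panel whose worst pair is perfectly
separable — dropping one of the colliding tags.

Spatial interactions, on a synthetic pattern where type B cells are
attracted to type A:

```r
pp <- simulate_point_pattern(c(A = 150, B = 150, C = 150), 1000, 1000,
                             mode = "attracted",
                             mode_params = list(pair = c("A", "B"),
                                                radius = 15, prob = 0.8),
                             seed = 9)
nn_adjacency_ratio(pp, "A", n_shuffles = 100, seed = 10)
#> Heterotypic NN adjacency around 'A' (100 shuffles):
#>   observed null_mean ratio      p
#> B      106     75.31 1.408 0.0099
#> C       44     74.69 0.589 1.0000
```

B cells appear as the nearest heterotypic neighbor of A cells 1.4 times
more often than label permutation predicts (empirical p = 0.0099).

See the vignette (`vignettes/intensity-barcoding.Rmd`) for the model,
its assumptions, and every numerical convention.

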