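#' Synthetic intensity-generator configuration
#'
#' Parameters of the per-cell measurement model used to emulate split-FP
#' intensity data. Each cell of a population carrying copy numbers
#' `(c, g, r)` is simulated as
#' \deqn{I_{ch} = s_i \cdot E(c_{ch}) \cdot e^{\epsilon_{ch}} + B,}
#' where `s_i = exp(N(0, sigma_expr))` is a shared per-cell expression
#' scale, `E(.)` is [expected_signal()], `epsilon_ch ~ N(0, sigma_chan)`
#' is per-channel multiplicative noise, and `B ~ N(bg_mean, bg_sd)` is
#' additive background; values are clamped at zero.
#'
#' Defaults encode the study conditions the generator emulates: a
#' 1.7-fold brightness gain per copy-number doubling (the measured
#' microscopy value; the ideal complementation model gives 2), and noise
#' magnitudes calibrated so that the four-level single-channel experiment
#' classifies at roughly 95% accuracy.
#'
#' @param amp per-doubling amplification factor (dimensionless; 2 = ideal
#'   linear brightness in copy number).
#' @param base_brightness single-repeat channel brightness (a.u.).
#' @param sigma_expr SD of the log per-cell expression scale.
#' @param sigma_chan SD of the log per-channel multiplicative noise.
#' @param bg_mean,bg_sd additive background mean and SD (a.u.).
#' @param ref_brightness brightness scale of the reference channel (a.u.).
#' @param n_cells_per_population cells simulated per tag.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(amp = 1.7, base_brightness = 100,
                             sigma_expr = 0.4, sigma_chan = 0.1,
                             bg_mean = 5, bg_sd = 2,
                             ref_brightness = 100,
                             n_cells_per_population = 500, seed = NULL) {
  stopifnot(amp > 0, base_brightness > 0, ref_brightness > 0,
            sigma_expr >= 0, sigma_chan >= 0, bg_sd >= 0,
            n_cells_per_population >= 1)
  structure(list(amp = amp, base_brightness = base_brightness,
                 sigma_expr = sigma_expr, sigma_chan = sigma_chan,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 ref_brightness = ref_brightness,
                 n_cells_per_population = as.integer(n_cells_per_population),
                 seed = seed),
            class = "generator_config")
}

#' Expected complemented brightness of a tandem FP11 tag
#'
#' Sub-linear signal amplification: each doubling of the repeat count
#' multiplies brightness by `amp`, i.e.
#' `E(n) = base * amp^log2(n)` for `n >= 1` and `E(0) = 0`. At the ideal
#' value `amp = 2` this reduces to brightness exactly linear in copy
#' number (an 8-repeat tag is 8x a single repeat); the measured
#' microscopy behavior corresponds to `amp` around 1.7.
#'
#' @param copy_number nonnegative integer repeat count (vectorized).
#' @param config a [generator_config()]; or override `amp`/`base`
#'   directly.
#' @param amp,base amplification factor and single-repeat brightness,
#'   defaulting to the config values.
#' @return Expected brightness in arbitrary units.
#' @examples
#' expected_signal(8, amp = 2, base = 1)    # 8: ideal linear case
#' expected_signal(4, amp = 1.7, base = 1)  # 1.7^2 = 2.89
#' @export
expected_signal <- function(copy_number, config = generator_config(),
                            amp = config$amp, base = config$base_brightness) {
  stopifnot(all(copy_number >= 0), all(copy_number == floor(copy_number)),
            amp > 0, base > 0)
  out <- numeric(length(copy_number))
  pos <- copy_number > 0
  out[pos] <- base * amp^log2(copy_number[pos])
  out
}

#' Simulate a per-cell intensity table for a tag panel
#'
#' Draws `n_cells_per_population` cells for every tag in `panel` under
#' the measurement model described in [generator_config()]. The true
#' population (tag id) is recorded per cell, making the table directly
#' usable as labeled training data.
#'
#' @param panel a [tag_library()] or any data.frame with columns
#'   `tag_id`, `c_C`, `c_G`, `c_R`.
#' @param config a [generator_config()].
#' @param n_cells cells per population; defaults to the config value.
#' @param seed integer seed; defaults to the config seed.
#' @return A cell table (data.frame): `cell_id`, `population`, `ch_C`,
#'   `ch_G`, `ch_R`, `ch_ref`. Identical config and seed give a
#'   bit-identical table.
#' @export
simulate_intensity_table <- function(panel, config = generator_config(),
                                     n_cells = config$n_cells_per_population,
                                     seed = config$seed) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1,
            all(c("tag_id", "c_C", "c_G", "c_R") %in% names(panel)),
            n_cells >= 1)
  with_seed(seed, {
    n_pop <- nrow(panel)
    n_tot <- n_pop * n_cells
    pop <- rep(panel$tag_id, each = n_cells)
    s <- exp(rnorm(n_tot, 0, config$sigma_expr))
    channel <- function(copies) {
      mu <- rep(expected_signal(copies, config), each = n_cells)
      raw <- s * mu * exp(rnorm(n_tot, 0, config$sigma_chan)) +
        rnorm(n_tot, config$bg_mean, config$bg_sd)
      pmax(raw, 0)
    }
    ch_C <- channel(panel$c_C)
    ch_G <- channel(panel$c_G)
    ch_R <- channel(panel$c_R)
    ch_ref <- pmax(s * config$ref_brightness *
                     exp(rnorm(n_tot, 0, config$sigma_chan)) +
                     rnorm(n_tot, config$bg_mean, config$bg_sd), 0)
    data.frame(cell_id = sprintf("cell%06d", seq_len(n_tot)),
               population = pop, ch_C = ch_C, ch_G = ch_G, ch_R = ch_R,
               ch_ref = ch_ref, stringsAsFactors = FALSE)
  })
}

#' Simulate a labeled spatial point pattern
#'
#' Generates cell centroids with population labels in a rectangular
#' region, under one of three spatial regimes:
#' \describe{
#'   \item{`random`}{uniform positions with uniformly shuffled labels
#'     (complete spatial randomness for every label).}
#'   \item{`clustered`}{a Thomas-style parent--offspring process per
#'     label: `mode_params$n_parents` uniformly placed parents, offspring
#'     scattered around them with Gaussian dispersion
#'     `mode_params$offspring_sd`.}
#'   \item{`attracted`}{starts from the random regime, then relocates
#'     each point of label `mode_params$pair[2]` with probability
#'     `mode_params$prob` to within `mode_params$radius` of a random
#'     point of label `mode_params$pair[1]`, creating heterotypic
#'     attraction.}
#' }
#'
#' @param n_per_label named integer vector: points per label.
#' @param width,height region dimensions (micrometers).
#' @param mode `"random"`, `"clustered"`, or `"attracted"`.
#' @param mode_params list of regime parameters (see Details).
#' @param seed integer seed.
#' @return A [point_pattern()] with `region_area = width * height`.
#' @export
simulate_point_pattern <- function(n_per_label, width = 1000, height = 1000,
                                   mode = c("random", "clustered", "attracted"),
                                   mode_params = list(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(width > 0, height > 0, all(n_per_label >= 0))
  n_tot <- sum(n_per_label)
  if (n_tot == 0L) stop("at least one point is required")
  labs <- names(n_per_label)
  if (is.null(labs)) labs <- paste0("type", seq_along(n_per_label))
  with_seed(seed, {
    if (mode == "clustered") {
      n_par <- if (is.null(mode_params$n_parents)) 10L else mode_params$n_parents
      osd <- if (is.null(mode_params$offspring_sd)) min(width, height) / 50
             else mode_params$offspring_sd
      xs <- ys <- numeric(0); ls <- character(0)
      for (j in seq_along(n_per_label)) {
        n <- n_per_label[j]
        px <- runif(n_par, 0, width); py <- runif(n_par, 0, height)
        pick <- sample.int(n_par, n, replace = TRUE)
        xs <- c(xs, pmin(pmax(px[pick] + rnorm(n, 0, osd), 0), width))
        ys <- c(ys, pmin(pmax(py[pick] + rnorm(n, 0, osd), 0), height))
        ls <- c(ls, rep(labs[j], n))
      }
    } else {
      xs <- runif(n_tot, 0, width)
      ys <- runif(n_tot, 0, height)
      ls <- sample(rep(labs, n_per_label))
      if (mode == "attracted") {
        pair <- mode_params$pair
        if (is.null(pair) || length(pair) != 2L)
          stop("mode_params$pair = c(source_label, attracted_label) required")
        radius <- if (is.null(mode_params$radius)) min(width, height) / 50
                  else mode_params$radius
        prob <- if (is.null(mode_params$prob)) 0.8 else mode_params$prob
        src <- which(ls == pair[1L]); tgt <- which(ls == pair[2L])
        if (length(src) == 0L || length(tgt) == 0L)
          stop("both labels of the attraction pair must be present")
        move <- tgt[runif(length(tgt)) < prob]
        anchor <- src[sample.int(length(src), length(move), replace = TRUE)]
        theta <- runif(length(move), 0, 2 * pi)
        rad <- radius * sqrt(runif(length(move)))
        xs[move] <- pmin(pmax(xs[anchor] + rad * cos(theta), 0), width)
        ys[move] <- pmin(pmax(ys[anchor] + rad * sin(theta), 0), height)
      }
    }
    point_pattern(xs, ys, ls, region_area = width * height)
  })
}
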