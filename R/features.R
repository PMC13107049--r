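# Channel columns every intensity table is expected to carry.
CHANNELS <- c("ch_C", "ch_G", "ch_R")

#' Subtract control-derived background from channel intensities
#'
#' Per-channel background levels (typically medians from non-fluorescent
#' control cells) are subtracted from the corresponding intensities and
#' negative results are clamped at zero. The number of clamped values is
#' attached as attribute `"n_clamped"`.
#'
#' @param table cell table with the channels named in `control_medians`.
#' @param control_medians named numeric vector of nonnegative background
#'   levels, e.g. `c(ch_C = 12, ch_G = 8, ch_R = 10)`.
#' @return The corrected table.
#' @export
subtract_background <- function(table, control_medians) {
  stopifnot(is.data.frame(table), is.numeric(control_medians),
            all(control_medians >= 0))
  chans <- names(control_medians)
  if (is.null(chans) || any(!nzchar(chans)))
    stop("control_medians must be a named vector of channel medians")
  missing <- setdiff(chans, names(table))
  if (length(missing))
    stop("channels absent from the table: ", paste(missing, collapse = ", "))
  n_clamped <- 0L
  for (ch in chans) {
    v <- table[[ch]] - control_medians[[ch]]
    n_clamped <- n_clamped + sum(v < 0)
    table[[ch]] <- pmax(v, 0)
  }
  attr(table, "n_clamped") <- n_clamped
  table
}

#' Normalize channels by their pooled global medians
#'
#' Each channel is divided by its median computed across all cells of
#' all populations combined, putting the three fluorophores on a common
#' scale (post-normalization pooled median of every channel is 1).
#'
#' @param table cell table.
#' @param channels channel columns to normalize.
#' @return The normalized table, with the medians used attached as
#'   attribute `"global_medians"`.
#' @export
normalize_global_median <- function(table, channels = CHANNELS) {
  stopifnot(is.data.frame(table))
  channels <- intersect(channels, names(table))
  if (!length(channels)) stop("no channel columns found in the table")
  med <- vapply(channels, function(ch) median(table[[ch]]), numeric(1))
  zero <- channels[med <= 0]
  if (length(zero))
    stop("degenerate channel with non-positive pooled median: ",
         paste(zero, collapse = ", "))
  for (ch in channels) table[[ch]] <- table[[ch]] / med[[ch]]
  attr(table, "global_medians") <- med
  table
}

#' Two-channel polar angle
#'
#' Maps a nonnegative intensity pair to the angle
#' `atan2(numerator, denominator)` in degrees, ranging over \[0, 90\]:
#' 0 when the numerator channel is dark, 90 when the denominator channel
#' is dark. Scale-free: `(k a, k b)` gives the same angle as `(a, b)`
#' for any `k > 0`. The degenerate pair `(0, 0)` yields `NA`.
#'
#' @param numerator,denominator nonnegative intensities (vectorized).
#' @return Angle in degrees.
#' @examples
#' polar_angle(1, 1)        # 45
#' polar_angle(1, sqrt(3))  # 30
#' @export
polar_angle <- function(numerator, denominator) {
  stopifnot(all(numerator >= 0, na.rm = TRUE),
            all(denominator >= 0, na.rm = TRUE))
  out <- atan2(numerator, denominator) * 180 / pi
  out[numerator == 0 & denominator == 0] <- NA_real_
  out
}

#' Spherical-angle features of trichromatic intensities
#'
#' Transforms per-cell `(ch_C, ch_G, ch_R)` intensities into the radial
#' magnitude and two scale-free angles:
#' \deqn{r = \sqrt{C^2 + G^2 + R^2},\quad
#'       Angle_{CvsG} = \arctan(G / C),\quad
#'       Angle_{RvsCG} = \arccos(R / r),}
#' all angles in degrees within \[0, 90\] for nonnegative inputs. The
#' two-argument arctangent is used so `C = 0` maps to 90 degrees; when
#' `C = G = 0` but `R > 0` the first angle is set to 0 by convention
#' (the second angle, 0, carries all the information). Cells with
#' `r = 0` are flagged invalid (`valid = FALSE`, angles `NA`).
#'
#' @param table cell table with `ch_C`, `ch_G`, `ch_R` (nonnegative,
#'   background-corrected and median-normalized upstream).
#' @return The table with columns `r`, `angle_cvsg_deg`,
#'   `angle_rvscg_deg` and `valid` appended; the count of invalid cells
#'   is attached as attribute `"n_invalid"`.
#' @export
spherical_features <- function(table) {
  stopifnot(is.data.frame(table), all(CHANNELS %in% names(table)))
  x <- table$ch_C; y <- table$ch_G; z <- table$ch_R
  if (any(!is.finite(c(x, y, z)))) stop("non-finite channel intensity")
  if (any(c(x, y, z) < 0)) stop("negative intensity; clamp upstream")
  r <- sqrt(x^2 + y^2 + z^2)
  valid <- r > 0
  cvsg <- atan2(y, x) * 180 / pi
  cvsg[x == 0 & y == 0] <- 0          # pure-red convention
  rvscg <- rep(NA_real_, length(r))
  rvscg[valid] <- acos(pmin(z[valid] / r[valid], 1)) * 180 / pi
  cvsg[!valid] <- NA_real_
  table$r <- r
  table$angle_cvsg_deg <- cvsg
  table$angle_rvscg_deg <- rvscg
  table$valid <- valid
  attr(table, "n_invalid") <- sum(!valid)
  table
}

#' Relative brightness of split-FP constructs
#'
#' Quantifies split-construct brightness relative to the full-length
#' fluorophore via the three-step normalization procedure:
#' (1) per-cell `signal / reference` ratios of the full-length
#' population define the normalization standard (their median);
#' (2) each gated split-construct cell's `signal / reference` ratio is
#' computed; (3) each ratio is divided by the standard. By construction
#' the full-length population's own median relative brightness is 1.
#'
#' @param split_cells,fulllength_cells cell tables carrying the columns
#'   named by `signal` and `reference`.
#' @param signal channel column holding the (split or full-length) FP
#'   signal.
#' @param reference expression-normalization channel column (EBFP role).
#' @param gate reporter-positivity threshold: split cells with
#'   `reference <= gate` are excluded before step (2).
#' @return Numeric vector of per-cell relative brightness values for the
#'   gated split cells; the standard is attached as attribute
#'   `"standard"`.
#' @export
relative_brightness <- function(split_cells, fulllength_cells,
                                signal = "ch_C", reference = "ch_ref",
                                gate = 0) {
  for (tab in list(split_cells, fulllength_cells))
    if (!all(c(signal, reference) %in% names(tab)))
      stop("signal/reference columns missing from a table")
  standard <- median(fulllength_cells[[signal]] /
                       fulllength_cells[[reference]])
  if (!is.finite(standard) || standard <= 0)
    stop("degenerate normalization standard (median full-length ratio <= 0)")
  gated <- split_cells[split_cells[[reference]] > gate, , drop = FALSE]
  if (nrow(gated) == 0L) stop("gate removed every split-construct cell")
  out <- (gated[[signal]] / gated[[reference]]) / standard
  attr(out, "standard") <- standard
  out
}
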