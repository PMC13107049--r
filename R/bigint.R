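# Exact arbitrary-precision nonnegative integers, stored as decimal digit
# strings. Only the handful of operations the tag-library combinatorics
# need: multiply / exact-divide by a machine integer, decrement, powers of
# two, binomial coefficients, and scientific-notation formatting.

big_digits <- function(x) as.integer(strsplit(x, "", fixed = TRUE)[[1]])

big_collapse <- function(d) {
  d <- d[cumsum(d != 0L) > 0L | seq_along(d) == length(d)]  # strip leading 0s
  paste(d, collapse = "")
}

big_mul_small <- function(x, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^26)
  d <- rev(big_digits(x)) * m
  carry <- 0
  out <- integer(0)
  i <- 1L
  while (i <= length(d) || carry > 0) {
    v <- carry + if (i <= length(d)) d[i] else 0
    out[i] <- v %% 10
    carry <- v %/% 10
    i <- i + 1L
  }
  big_collapse(rev(out))
}

# exact division; errors if a remainder is left
big_div_small <- function(x, m) {
  stopifnot(m >= 1, m == floor(m), m < 2^26)
  d <- big_digits(x)
  out <- integer(length(d))
  rem <- 0
  for (i in seq_along(d)) {
    v <- rem * 10 + d[i]
    out[i] <- v %/% m
    rem <- v %% m
  }
  if (rem != 0) stop("big_div_small: division is not exact")
  big_collapse(out)
}

big_dec1 <- function(x) {
  d <- rev(big_digits(x))
  i <- 1L
  while (d[i] == 0L) { d[i] <- 9L; i <- i + 1L }
  d[i] <- d[i] - 1L
  big_collapse(rev(d))
}

#' Arbitrary-precision integer wrapper
#'
#' Light wrapper used for counts that overflow double precision (binomial
#' coefficients, label capacities). Holds the exact decimal digit string.
#'
#' @param x character string of decimal digits, or a nonnegative integer.
#' @return An object of class `bigint`.
#' @keywords internal
bigint <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x >= 0, x == floor(x), x < 2^53)
    x <- sprintf("%.0f", x)
  }
  stopifnot(is.character(x), grepl("^[0-9]+$", x))
  structure(list(digits = sub("^0+(?=.)", "", x, perl = TRUE)),
            class = "bigint")
}

#' @export
as.character.bigint <- function(x, ...) x$digits

#' @export
as.double.bigint <- function(x, ...) as.numeric(x$digits)

#' @export
print.bigint <- function(x, ...) {
  cat(x$digits, "\n")
  invisible(x)
}

#' @export
format.bigint <- function(x, ...) x$digits

#' @export
`==.bigint` <- function(e1, e2) {
  d1 <- if (inherits(e1, "bigint")) e1$digits else as.character(bigint(e1))
  d2 <- if (inherits(e2, "bigint")) e2$digits else as.character(bigint(e2))
  d1 == d2
}

#' Format an exact integer in scientific notation
#'
#' Rounds the decimal digit string of a [bigint] to a requested number of
#' significant figures, e.g. `"2e+20"` at one significant figure.
#'
#' @param x a `bigint` (or nonnegative numeric below 2^53).
#' @param sig number of significant figures (>= 1).
#' @return A character scalar like `"2.16e+20"`.
#' @examples
#' format_sci(subset_count(96, 20), sig = 1)
#' @export
format_sci <- function(x, sig = 1) {
  if (!inherits(x, "bigint")) x <- bigint(x)
  stopifnot(sig >= 1, sig == floor(sig))
  d <- big_digits(x$digits)
  expo <- length(d) - 1L
  if (length(d) <= sig) {
    mant_digits <- c(d, rep(0L, sig - length(d)))
  } else {
    keep <- d[seq_len(sig)]
    if (d[sig + 1L] >= 5L) {  # round half up
      i <- sig
      keep[i] <- keep[i] + 1L
      while (i > 1L && keep[i] == 10L) { keep[i] <- 0L; i <- i - 1L; keep[i] <- keep[i] + 1L }
      if (keep[1L] == 10L) { keep <- c(1L, rep(0L, sig - 1L)); expo <- expo + 1L }
    }
    mant_digits <- keep
  }
  mant <- if (sig == 1L) as.character(mant_digits) else
    paste0(mant_digits[1L], ".", paste(mant_digits[-1L], collapse = ""))
  sprintf("%se+%02d", mant, expo)
}
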