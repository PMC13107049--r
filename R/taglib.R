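#' Enumerate a trichromatic FP11 tag library
#'
#' A tag is a triple of copy numbers `(c_C, c_G, c_R)` for the CFP2,
#' mNG3Asp and sfCherry3Csp eleventh-strand repeats, each drawn from a
#' configured level set. Enumeration keeps every triple whose summed
#' repeat count does not exceed `max_total`; the all-zero (unlabeled)
#' triple is excluded unless `include_null = TRUE`. With the default
#' levels \{0, 1, 2, 4, 8\} and `max_total = 12` this yields the 96-tag
#' library used for panel screening.
#'
#' @param levels allowed copy numbers per channel (nonnegative integers).
#' @param max_total maximum summed repeats across the three channels;
#'   `Inf` for unbounded.
#' @param include_null keep the `(0,0,0)` triple?
#' @return A `tag_library`: a data.frame with columns `tag_id`, `c_C`,
#'   `c_G`, `c_R`, sorted lexicographically by `(c_C, c_G, c_R)`, with
#'   the generating parameters stored as attributes.
#' @examples
#' lib <- tag_library()            # the 96-tag screening library
#' nrow(lib)
#' head(lib$tag_id)
#' @export
tag_library <- function(levels = c(0, 1, 2, 4, 8), max_total = 12,
                        include_null = FALSE) {
  stopifnot(length(levels) >= 1, all(levels >= 0), all(levels == floor(levels)),
            !anyDuplicated(levels), max_total >= 0)
  levels <- sort(as.integer(levels))
  g <- expand.grid(c_R = levels, c_G = levels, c_C = levels,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("c_C", "c_G", "c_R")]
  g <- g[order(g$c_C, g$c_G, g$c_R), , drop = FALSE]
  tot <- g$c_C + g$c_G + g$c_R
  keep <- tot <= max_total & (include_null | tot > 0)
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L)
    stop("tag library is empty after applying the max_total/null filters")
  rownames(g) <- NULL
  out <- data.frame(tag_id = tag_id(g$c_C, g$c_G, g$c_R), g,
                    stringsAsFactors = FALSE)
  structure(out, levels_set = levels, max_total = max_total,
            include_null = include_null,
            class = c("tag_library", "data.frame"))
}

#' Canonical tag identifier
#'
#' Renders copy-number triples as machine-readable strings of the form
#' `"C1G2R4"`.
#'
#' @param c_C,c_G,c_R nonnegative integer copy numbers (vectorized).
#' @return Character vector of canonical ids.
#' @seealso [parse_tag_id()] for the inverse.
#' @export
tag_id <- function(c_C, c_G, c_R) {
  stopifnot(all(c(c_C, c_G, c_R) >= 0),
            all(c(c_C, c_G, c_R) == floor(c(c_C, c_G, c_R))))
  sprintf("C%dG%dR%d", as.integer(c_C), as.integer(c_G), as.integer(c_R))
}

#' Parse a tag identifier
#'
#' Accepts the canonical `"C1G2R4"` form and the parenthesized triple
#' form `"(1,2,4)"` used in figure legends.
#'
#' @param id character vector of tag ids.
#' @return A data.frame with columns `c_C`, `c_G`, `c_R`.
#' @export
parse_tag_id <- function(id) {
  stopifnot(is.character(id))
  canon <- "^C([0-9]+)G([0-9]+)R([0-9]+)$"
  paren <- "^\\(\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*\\)$"
  out <- matrix(NA_integer_, nrow = length(id), ncol = 3L)
  for (i in seq_along(id)) {
    pat <- if (grepl(canon, id[i])) canon else if (grepl(paren, id[i])) paren
      else stop("unparseable tag id: ", id[i])
    m <- regmatches(id[i], regexec(pat, id[i]))[[1L]]
    out[i, ] <- as.integer(m[2:4])
  }
  data.frame(c_C = out[, 1L], c_G = out[, 2L], c_R = out[, 3L])
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("FP11 tag library: %d tags over levels {%s}, max total %s%s\n",
              nrow(x), paste(attr(x, "levels_set"), collapse = ", "),
              format(attr(x, "max_total")),
              if (attr(x, "include_null")) ", null tag included" else ""))
  print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more tags\n")
  invisible(x)
}

#' Number of binary on/off color combinations
#'
#' The classic capacity of `n` independently switchable colors:
#' `2^n - 1` combinations, excluding the all-off state (e.g. 31 for five
#' colors). Exact for any `n` via arbitrary-precision arithmetic.
#'
#' @param n_colors number of colors (>= 1).
#' @return A [bigint]; coerce with `as.character()` or `as.numeric()`.
#' @examples
#' as.numeric(binary_label_capacity(5))  # 31
#' @export
binary_label_capacity <- function(n_colors) {
  if (!is.numeric(n_colors) || length(n_colors) != 1L || n_colors < 1 ||
      n_colors != floor(n_colors))
    stop("n_colors must be a positive integer")
  p <- "1"
  for (i in seq_len(n_colors)) p <- big_mul_small(p, 2)
  bigint(big_dec1(p))
}

#' Exact binomial coefficient
#'
#' `C(n, k)` computed exactly in arbitrary precision, for counting
#' candidate panels (e.g. the ~2e20 ways of choosing 20 tags from 96).
#'
#' @param n,k nonnegative integers with `k <= n`.
#' @return A [bigint].
#' @examples
#' format_sci(subset_count(96, 20), sig = 1)  # "2e+20"
#' @export
subset_count <- function(n, k) {
  stopifnot(is.numeric(n), is.numeric(k), n >= 0, k >= 0,
            n == floor(n), k == floor(k))
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  acc <- "1"
  for (i in seq_len(k)) {   # C(n, i) = C(n, i-1) * (n - i + 1) / i, exact
    acc <- big_mul_small(acc, n - i + 1)
    acc <- big_div_small(acc, i)
  }
  bigint(acc)
}
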