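#' Percentage of a part relative to a whole
#'
#' Small arithmetic helper used throughout the package wherever a count is
#' expressed as a percentage of a denominator (context shares, strand shares,
#' methylated fraction, ...). Returns `NA` when the denominator is not
#' positive instead of dividing by zero.
#'
#' @param x Numeric vector of parts (counts).
#' @param n Numeric scalar or vector of wholes (denominators).
#' @return `100 * x / n`, with `NA` where `n <= 0`.
#' @examples
#' pct(5, 10)      # 50
#' pct(1, 3)       # 33.33...
#' @export
pct <- function(x, n) {
  out <- 100 * x / n
  out[!is.finite(n) | n <= 0] <- NA_real_
  out
}

#' Signed percent change between two counts
#'
#' Computes `100 * (count_test - count_ref) / count_ref`, keeping the sign:
#' a decrease is negative. Used to express changes in methylated-gene counts
#' between conditions.
#'
#' @param count_ref Reference count (must be > 0 for a defined result).
#' @param count_test Test count.
#' @return Percent change (numeric). `NA` with a warning when `count_ref`
#'   is zero.
#' @examples
#' percent_change(100, 119)  # +19
#' percent_change(100, 93)   # -7
#' @export
percent_change <- function(count_ref, count_test) {
  stopifnot(is.numeric(count_ref), is.numeric(count_test))
  out <- 100 * (count_test - count_ref) / count_ref
  bad <- count_ref == 0
  if (any(bad)) {
    warning("percent_change undefined for zero reference count; returning NA")
    out[bad] <- NA_real_
  }
  out
}

# random composition of `total` into `parts` integers, each >= `min`
.rand_composition <- function(total, parts, min = 1L) {
  if (parts == 0L) return(integer(0))
  slack <- total - parts * min
  if (slack < 0L) stop("cannot split ", total, " into ", parts, " parts of >= ", min)
  as.integer(stats::rmultinom(1L, slack, rep(1, parts))[, 1L] + min)
}

# deterministic sub-seed for a condition/replicate stream, kept < 2^31
.condition_seed <- function(seed, condition, replicate = 1L) {
  h <- 0
  for (k in utf8ToInt(condition)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) * 131071 + h * 257 + replicate) %% 2147483647L)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

.is_fraction <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
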