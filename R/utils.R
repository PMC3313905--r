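# Small shared helpers: seed management, geometric means, input checks.

#' Geometric mean
#'
#' Geometric mean of positive values, computed on the log2 scale for
#' numerical stability. Non-finite values can be dropped with `na.rm`.
#'
#' @param x Numeric vector of positive values.
#' @param na.rm Drop non-finite values before averaging.
#' @return A single number, or `NA` if no usable values remain or any value
#'   is non-positive.
#' @examples
#' geometric_mean(c(8, 1, 1)) # 2
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(!is.finite(x)) || any(x <= 0)) return(NA_real_)
  2^mean(log2(x))
}

# Derive `n` child seeds (< 2^31) from one master seed without disturbing
# the caller's RNG state.
split_seed <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Evaluate a polynomial with coefficients in increasing order of degree.
polyval_asc <- function(coefs, x) {
  out <- rep(0, length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}
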