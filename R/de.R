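# Intensity-dependent differential-expression calling: a sliding rank
# window over A supplies local mean/SD of M, the Z-score against them is
# thresholded two-sided at the requested confidence, and genes are
# labeled U (up), D (down) or S (unchanged).

#' Sliding-window local statistics over the M-A plot
#'
#' Features are sorted by mean log intensity `A`; each feature's local mean
#' and SD of `M` are computed over a window of `ceiling(window_frac * n)`
#' nearest ranks centred on it. At the extremes the window keeps its full
#' size by shifting inward, so `window_frac = 1` reproduces the global
#' mean/SD for every feature.
#'
#' @param M,A Numeric vectors (log ratio and mean log intensity).
#' @param window_frac Window width as a fraction of the number of features
#'   (default 20%).
#' @param gene_id Optional identifiers used as a stable tie-break when
#'   sorting by `A`.
#' @return A tibble in the input order with `mu_local` and `sd_local`.
#' @export
sliding_window_stats <- function(M, A, window_frac = 0.20, gene_id = NULL) {
  n <- length(M)
  if (n < 10) abort("at least 10 features are required.")
  if (length(A) != n) abort("`M` and `A` must have equal length.")
  if (!is_proportion(window_frac) || window_frac == 0) {
    abort("`window_frac` must lie in (0, 1].")
  }
  ord <- if (is.null(gene_id)) order(A) else order(A, gene_id)
  ms <- M[ord]
  w <- max(2L, as.integer(ceiling(window_frac * n)))
  half <- (w - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmin(pmax(1L, i - half), n - w + 1L)
  hi <- lo + w - 1L
  cs <- c(0, cumsum(ms))
  cs2 <- c(0, cumsum(ms^2))
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  mu <- s / w
  v <- pmax(0, (s2 - s^2 / w) / (w - 1L))
  out <- tibble(mu_local = numeric(n), sd_local = numeric(n))
  out$mu_local[ord] <- mu
  out$sd_local[ord] <- sqrt(v)
  out
}

#' Classify differential expression from local Z-scores
#'
#' `Z = (M - mu_local) / sd_local`, thresholded two-sided at the normal
#' critical value of the confidence level: `U` when `Z >= z_crit`, `D`
#' when `Z <= -z_crit`, `S` otherwise.
#'
#' @param M Log ratios.
#' @param mu_local,sd_local Local window statistics
#'   ([sliding_window_stats()]).
#' @param confidence Two-sided confidence level (default 0.95, giving
#'   `z_crit` of about 1.96).
#' @param allow_degenerate With `FALSE` (default) a zero `sd_local` is an
#'   error; with `TRUE` such features get `Z = 0`.
#' @return A tibble with `Z` and `label`, plus attribute `z_crit`.
#' @export
classify_de <- function(M, mu_local, sd_local, confidence = 0.95,
                        allow_degenerate = FALSE) {
  if (!is_proportion(confidence) || confidence == 0 || confidence == 1) {
    abort("`confidence` must lie in (0, 1).")
  }
  zero <- is.finite(sd_local) & sd_local == 0
  if (any(zero) && !allow_degenerate) {
    abort("sd_local is zero in some windows; set `allow_degenerate = TRUE` to assign Z = 0 there.")
  }
  z_crit <- qnorm(1 - (1 - confidence) / 2)
  z <- (M - mu_local) / sd_local
  z[zero] <- 0
  label <- dplyr::case_when(
    z >= z_crit ~ "U",
    z <= -z_crit ~ "D",
    is.na(z) ~ NA_character_,
    TRUE ~ "S"
  )
  out <- tibble(Z = z, label = label)
  attr(out, "z_crit") <- z_crit
  out
}

#' Call differential expression per experiment
#'
#' Applies the sliding-window Z-score to each experiment of a unified long
#' matrix carrying both `M` and `A`, then labels each gene U/D/S.
#'
#' @param unified Long tibble with `gene_id`, `experiment_id`, `M`, `A`.
#' @param window_frac,confidence,allow_degenerate See
#'   [sliding_window_stats()] and [classify_de()].
#' @return A long tibble with `mu_local`, `sd_local`, `Z` and `label`
#'   added, of class `gc_de`; attribute `z_crit` holds the threshold.
#' @export
call_de <- function(unified, window_frac = 0.20, confidence = 0.95,
                    allow_degenerate = FALSE) {
  assert_columns(unified, c("gene_id", "experiment_id", "M", "A"), "unified")
  out <- unified |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_modify(function(df, key) {
      st <- sliding_window_stats(df$M, df$A, window_frac, df$gene_id)
      cl <- classify_de(df$M, st$mu_local, st$sd_local, confidence,
                        allow_degenerate)
      dplyr::bind_cols(df, st, cl)
    }) |>
    dplyr::ungroup()
  attr(out, "z_crit") <- qnorm(1 - (1 - confidence) / 2)
  class(out) <- c("gc_de", class(out))
  out
}
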