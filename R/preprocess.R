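# Per-slide preprocessing: robust loess-based background correction under a
# multiplicative noise model, geometric-mean replicate averaging, iterative
# IQR outlier exclusion, M-A loess normalization, and the loop-design
# consistency filter. All intensities are log2 unless a column name is
# lower-case (fc, fa), which marks the absolute (linear) scale.

# Robust loess fit of y on x evaluated at `at`. surface = "direct" so that
# data lying exactly on a polynomial of the local degree is reproduced to
# machine precision.
robust_loess_fit <- function(x, y, at, span, degree, iterations) {
  if (diff(range(y)) == 0) return(rep(y[1], length(at))) # constant regression
  df <- data.frame(x = x, y = y)
  fit <- stats::loess(
    y ~ x, data = df, span = span, degree = degree, family = "gaussian",
    control = stats::loess.control(surface = "direct"))
  # Bisquare reweighting degenerates when the fit is already exact
  # (residual MAD 0), so only go robust when there is residual scatter.
  if (max(abs(fit$residuals)) > 1e-8 * (1 + max(abs(y)))) {
    fit <- stats::loess(
      y ~ x, data = df, span = span, degree = degree,
      family = "symmetric",
      control = stats::loess.control(surface = "direct",
                                     iterations = iterations))
  }
  as.numeric(predict(fit, newdata = data.frame(x = at)))
}

#' Robust loess-based background correction (rLsBC)
#'
#' Corrects the log2 foreground intensity of each channel by subtracting a
#' robust loess regression estimate of the log2 background as a function of
#' the log2 foreground, instead of the per-spot local background. This
#' treats background noise as acting multiplicatively on the raw
#' intensities: `Fc = F - Bl` on the log2 scale, `fc = 2^Fc` on the
#' absolute scale.
#'
#' @param slide A tibble with columns `feature_id`, `F_R`, `B_R`, `F_G`,
#'   `B_G` (log2 median foreground/background per channel). Extra columns
#'   are carried through.
#' @param span Loess smoothing parameter for the background regression.
#' @param degree Local polynomial degree of the background regression.
#' @param robust_iterations Bisquare reweighting iterations.
#' @return The input with columns `Bl_R`, `Bl_G` (fitted log2 background),
#'   `Fc_R`, `Fc_G` (log2 corrected foreground) and `fc_R`, `fc_G`
#'   (absolute corrected intensity) added. Features with missing
#'   intensities propagate as `NA`.
#' @export
background_correct_rlsbc <- function(slide, span = 0.3, degree = 1,
                                     robust_iterations = 4) {
  assert_columns(slide, c("feature_id", "F_R", "B_R", "F_G", "B_G"), "slide")
  if (span <= 0 || span > 1) abort("`span` must lie in (0, 1].")
  out <- slide
  for (ch in c("R", "G")) {
    f <- slide[[paste0("F_", ch)]]
    b <- slide[[paste0("B_", ch)]]
    ok <- is.finite(f) & is.finite(b)
    if (sum(ok) < 10) {
      abort(sprintf(
        "channel %s has %d valid features; at least 10 are required for the background regression.",
        ch, sum(ok)))
    }
    bl <- rep(NA_real_, nrow(slide))
    bl[is.finite(f)] <- robust_loess_fit(f[ok], b[ok], f[is.finite(f)],
                                         span, degree, robust_iterations)
    fc_log <- f - bl
    out[[paste0("Bl_", ch)]] <- bl
    out[[paste0("Fc_", ch)]] <- fc_log
    out[[paste0("fc_", ch)]] <- 2^fc_log
  }
  out
}

#' Average replicate slides by geometric mean
#'
#' Collapses the background-corrected replicate slides of one experiment to
#' a single averaged slide, taking the geometric mean of the absolute
#' corrected intensities per channel: `fa = (prod fc_r)^(1/n)`.
#'
#' A feature missing (or non-positive) in some replicates is averaged over
#' the available ones when at least `min_valid` remain, otherwise masked.
#' With a single replicate the slide passes through unchanged.
#'
#' @param corrected A tibble of corrected replicate rows with columns
#'   `feature_id`, `replicate_index`, `fc_R`, `fc_G`.
#' @param min_valid Minimum replicates a feature must be observed in
#'   (ignored when only one replicate exists).
#' @return A tibble with one row per feature: `fa_R`, `fa_G` and a logical
#'   `mask` (`TRUE` = usable).
#' @export
average_replicates <- function(corrected, min_valid = 2) {
  assert_columns(corrected,
                 c("feature_id", "replicate_index", "fc_R", "fc_G"),
                 "corrected slides")
  n_rep <- dplyr::n_distinct(corrected$replicate_index)
  need <- if (n_rep == 1L) 1L else min_valid
  out <- corrected |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      fa_R = if (sum(is.finite(.data$fc_R) & .data$fc_R > 0) >= need)
        geometric_mean(.data$fc_R[is.finite(.data$fc_R) & .data$fc_R > 0])
      else NA_real_,
      fa_G = if (sum(is.finite(.data$fc_G) & .data$fc_G > 0) >= need)
        geometric_mean(.data$fc_G[is.finite(.data$fc_G) & .data$fc_G > 0])
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(mask = is.finite(.data$fa_R) & is.finite(.data$fa_G))
  n_masked <- sum(!out$mask)
  if (n_masked > 0) {
    inform(sprintf("average_replicates: %d feature(s) masked (missing or non-positive in too many replicates).",
                   n_masked))
  }
  out
}

#' Iterative interquartile-range outlier mask
#'
#' Flags values deviating more than `k_iqr` interquartile distances from
#' the first or third quartile (type-7 quartiles). When `iterative`, the
#' quartiles are recomputed on the survivors until a fixed point is
#' reached, so that massive outliers cannot hide one another.
#'
#' @param values Numeric vector (non-finite entries are never kept).
#' @param k_iqr Multiplier on the IQR (default 3, "extreme" outliers).
#' @param iterative Recompute quartiles on survivors until stable.
#' @return Logical keep mask, same length as `values`. A constant vector is
#'   kept entirely (IQR 0, every value equal to both quartiles).
#' @export
remove_outliers_iqr <- function(values, k_iqr = 3, iterative = TRUE) {
  finite <- is.finite(values)
  if (sum(finite) < 4) abort("at least 4 finite values are required.")
  keep <- finite
  repeat {
    q <- quantile(values[keep], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    new_keep <- finite & values >= q[1] - k_iqr * iqr &
      values <= q[2] + k_iqr * iqr
    new_keep[!finite] <- FALSE
    if (!iterative || identical(new_keep, keep)) {
      keep <- new_keep
      break
    }
    if (sum(new_keep) < 4) break # refuse to iterate into degeneracy
    keep <- new_keep
  }
  keep
}

#' Compute the M-A representation of an averaged slide
#'
#' `M = log2(fa_R) - log2(fa_G)` (log ratio, red over green) and
#' `A = (log2(fa_R) + log2(fa_G)) / 2` (mean log intensity).
#'
#' @param averaged A tibble with `feature_id`, `fa_R`, `fa_G` (absolute
#'   intensities) and optionally `mask`.
#' @return The input with `M` and `A` added; non-positive or missing
#'   intensities yield `NA` and a `FALSE` mask.
#' @export
compute_ma <- function(averaged) {
  assert_columns(averaged, c("feature_id", "fa_R", "fa_G"), "averaged slide")
  ok <- is.finite(averaged$fa_R) & is.finite(averaged$fa_G) &
    averaged$fa_R > 0 & averaged$fa_G > 0
  out <- averaged
  r <- replace(averaged$fa_R, !ok, NA_real_)
  g <- replace(averaged$fa_G, !ok, NA_real_)
  out$M <- log2(r) - log2(g)
  out$A <- (log2(r) + log2(g)) / 2
  if ("mask" %in% names(out)) out$mask <- out$mask & ok else out$mask <- ok
  out
}

#' Intensity-dependent loess normalization of an M-A profile
#'
#' Fits a robust loess curve with a local quadratic model to the M-A
#' scatter and subtracts it, removing intensity-dependent dye bias:
#' `M_norm = M - loess(A)`. `A` is left unchanged.
#'
#' @param profile A tibble with `feature_id`, `M`, `A` (and optionally
#'   `mask`; masked features are excluded from the fit and left `NA`).
#' @param span Loess smoothing parameter (default 10% of the data).
#' @param degree Local polynomial degree (default quadratic).
#' @param robust_iterations Bisquare reweighting iterations.
#' @return The profile with `M` replaced by the normalized values.
#' @export
normalize_loess_ma <- function(profile, span = 0.10, degree = 2,
                               robust_iterations = 4) {
  assert_columns(profile, c("feature_id", "M", "A"), "M-A profile")
  ok <- is.finite(profile$M) & is.finite(profile$A)
  if ("mask" %in% names(profile)) ok <- ok & profile$mask
  n_ok <- sum(ok)
  if (n_ok < 20) abort("at least 20 usable features are required for M-A normalization.")
  if (floor(span * n_ok) < degree + 1) {
    abort(sprintf(
      "span %.3f gives local windows of fewer than %d points for %d features; use a larger span.",
      span, degree + 1, n_ok))
  }
  trend <- rep(NA_real_, nrow(profile))
  trend[ok] <- robust_loess_fit(profile$A[ok], profile$M[ok],
                                profile$A[ok], span, degree,
                                robust_iterations)
  out <- profile
  out$M <- ifelse(ok, profile$M - trend, NA_real_)
  out
}

#' Loop-design consistency filter
#'
#' For a loop of experiments (A vs B, B vs C, A vs C) the log ratios must
#' satisfy `M1 + M2 = M3` feature-wise, so the loop discrepancy
#' `LdF = M1 + M2 - M3` should ideally equal zero. Features whose `LdF`
#' deviates more than `n_sd` standard deviations from the mean `LdF` are
#' eliminated; the removal is intended to propagate to every downstream
#' analysis.
#'
#' @param profile1,profile2,profile3 Normalized M-A profiles (tibbles with
#'   `feature_id` and `M`) of the three loop experiments on a shared
#'   feature set.
#' @param n_sd Width of the retention band in SDs of `LdF` (default 2).
#' @return A tibble with `feature_id`, `ldf` and logical `keep`, carrying
#'   the scalar statistics as attributes `mean_ldf` and `sd_ldf`. Features
#'   with a missing `M` in any experiment get `keep = FALSE`.
#' @export
loop_design_filter <- function(profile1, profile2, profile3, n_sd = 2) {
  profs <- list(profile1, profile2, profile3)
  purrr::walk(profs, assert_columns, c("feature_id", "M"), "loop profile")
  ids <- purrr::map(profs, "feature_id")
  for (i in 2:3) {
    extra <- setdiff(ids[[i]], ids[[1]])
    miss <- setdiff(ids[[1]], ids[[i]])
    if (length(extra) > 0 || length(miss) > 0) {
      abort(sprintf(
        "feature sets differ between experiments: %d only in profile %d (%s), %d only in profile 1 (%s).",
        length(extra), i, paste(head(extra, 3), collapse = ", "),
        length(miss), paste(head(miss, 3), collapse = ", ")))
    }
  }
  m1 <- profile1$M[match(ids[[1]], profile1$feature_id)]
  m2 <- profile2$M[match(ids[[1]], profile2$feature_id)]
  m3 <- profile3$M[match(ids[[1]], profile3$feature_id)]
  ldf <- m1 + m2 - m3
  mu <- mean(ldf[is.finite(ldf)])
  sdv <- sd(ldf[is.finite(ldf)])
  keep <- is.finite(ldf) & abs(ldf - mu) <= n_sd * sdv
  out <- tibble(feature_id = ids[[1]], ldf = ldf, keep = keep)
  attr(out, "mean_ldf") <- mu
  attr(out, "sd_ldf") <- sdv
  out
}

#' Preprocess all replicate slides of one experiment
#'
#' Convenience wrapper chaining the per-slide stages: background
#' correction, geometric-mean replicate averaging, iterative IQR outlier
#' exclusion on the log2 averaged intensities of each channel, the M-A
#' transform, and intensity-dependent loess normalization.
#'
#' @param slides Tibble of raw log2 slide rows of one experiment
#'   (`feature_id`, `replicate_index`, `F_R`, `B_R`, `F_G`, `B_G`).
#' @param span_bg,span_ma Loess spans for the background and M-A fits.
#' @param iqr_k IQR multiplier for outlier exclusion.
#' @param robust_iterations Bisquare iterations for both loess fits.
#' @return A normalized M-A profile tibble: `feature_id`, `fa_R`, `fa_G`,
#'   `M`, `A`, `mask`.
#' @export
preprocess_experiment <- function(slides, span_bg = 0.3, span_ma = 0.10,
                                  iqr_k = 3, robust_iterations = 4) {
  assert_columns(slides, c("feature_id", "replicate_index",
                           "F_R", "B_R", "F_G", "B_G"), "slides")
  corrected <- slides |>
    dplyr::group_by(.data$replicate_index) |>
    dplyr::group_modify(~ background_correct_rlsbc(
      .x, span = span_bg, robust_iterations = robust_iterations)) |>
    dplyr::ungroup()
  averaged <- average_replicates(corrected)
  ok_r <- rep(FALSE, nrow(averaged))
  ok_g <- ok_r
  valid <- averaged$mask
  ok_r[valid] <- remove_outliers_iqr(log2(averaged$fa_R[valid]), k_iqr = iqr_k)
  ok_g[valid] <- remove_outliers_iqr(log2(averaged$fa_G[valid]), k_iqr = iqr_k)
  averaged$mask <- valid & ok_r & ok_g
  averaged |>
    compute_ma() |>
    normalize_loess_ma(span = span_ma,
                       robust_iterations = robust_iterations)
}
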