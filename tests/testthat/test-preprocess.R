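test_that("constant background is subtracted exactly", {
  slide <- make_slide(bg = function(f) rep(5, length(f)))
  out <- background_correct_rlsbc(slide)
  expect_equal(out$Bl_R, rep(5, nrow(slide)))
  expect_equal(out$Fc_R, slide$F_R - 5)
  expect_equal(out$Fc_G, slide$F_G - 5)
})

test_that("a linear background-vs-foreground trend is removed to machine precision", {
  slide <- make_slide(bg = function(f) 2 + 0.3 * f, seed = 4)
  out <- background_correct_rlsbc(slide)
  # closed-form oracle: the fitted background must equal the known line
  expect_equal(out$Bl_G, 2 + 0.3 * slide$F_G, tolerance = 1e-10)
  expect_equal(out$Fc_R, slide$F_R - (2 + 0.3 * slide$F_R),
               tolerance = 1e-10)
})

test_that("absolute corrected intensity is 2^Fc and NAs propagate", {
  slide <- make_slide(seed = 6)
  slide$F_R[3] <- NA
  out <- background_correct_rlsbc(slide)
  expect_equal(out$fc_R, 2^out$Fc_R)
  expect_equal(out$fc_G, 2^out$Fc_G)
  expect_true(is.na(out$Fc_R[3]) && is.na(out$fc_R[3]))
  i <- which(abs(out$Fc_G - 3) == min(abs(out$Fc_G - 3)))[1]
  expect_equal(out$fc_G[i], 2^out$Fc_G[i]) # Fc = 3 would give fc = 8
})

test_that("too few valid features aborts naming the channel", {
  slide <- make_slide(n = 12)
  slide$B_G[1:8] <- NA
  expect_error(background_correct_rlsbc(slide), "channel G")
})

test_that("replicate averaging takes the geometric mean", {
  reps <- tibble::tibble(
    feature_id = rep(c("a", "b", "c"), each = 3),
    replicate_index = rep(1:3, 3),
    fc_R = c(8, 1, 1, 2, 2, 2, 2, 8, 8),
    fc_G = c(4, 4, 4, 1, 1, 8, 27, 1, 1)
  )
  out <- average_replicates(reps)
  expect_equal(out$fa_R[out$feature_id == "a"], 2)  # (8*1*1)^(1/3)
  expect_equal(out$fa_R[out$feature_id == "b"], 2)  # idempotent on (x,x,x)
  expect_equal(out$fa_G[out$feature_id == "c"], 3)  # (27*1*1)^(1/3)
})

test_that("geometric-mean averaging is scale-equivariant", {
  withr::with_seed(8, {
    reps <- tibble::tibble(
      feature_id = rep(sprintf("f%02d", 1:20), each = 3),
      replicate_index = rep(1:3, 20),
      fc_R = runif(60, 1, 100), fc_G = runif(60, 1, 100)
    )
  })
  base <- average_replicates(reps)
  scaled <- average_replicates(dplyr::mutate(reps, fc_R = fc_R * 7,
                                             fc_G = fc_G * 7))
  expect_equal(scaled$fa_R, base$fa_R * 7)
  expect_equal(scaled$fa_G, base$fa_G * 7)
})

test_that("features missing in too many replicates are masked", {
  reps <- tibble::tibble(
    feature_id = rep(c("a", "b"), each = 3),
    replicate_index = rep(1:3, 2),
    fc_R = c(2, NA, NA, 2, 8, NA),
    fc_G = c(4, 4, 4, 4, 4, 4)
  )
  expect_message(out <- average_replicates(reps), "masked")
  expect_false(out$mask[out$feature_id == "a"])
  expect_equal(out$fa_R[out$feature_id == "b"], 4) # mean over the 2 present
})

test_that("the IQR filter keeps well-behaved values and drops extremes", {
  withr::with_seed(10, x <- rnorm(1e5))
  keep <- remove_outliers_iqr(x, k_iqr = 3)
  expect_lt(mean(!keep), 0.001) # Monte-Carlo: < 0.1% excluded at 3 IQR
  y <- c(runif(50, 2, 16), 1e6)
  keep2 <- remove_outliers_iqr(y)
  expect_identical(which(!keep2), 51L)
  expect_true(all(remove_outliers_iqr(rep(3, 10)))) # constant: IQR 0, all kept
  expect_error(remove_outliers_iqr(c(1, 2, NA)), "4 finite")
})

test_that("the M-A transform is forced by its definition", {
  df <- tibble::tibble(feature_id = c("a", "b", "c"),
                       fa_R = c(4, 5, -1), fa_G = c(1, 5, 2))
  out <- compute_ma(df)
  expect_equal(out$M[1], 2)
  expect_equal(out$A[1], 1)
  expect_equal(out$M[2], 0)
  expect_true(is.na(out$M[3]) && !out$mask[3]) # non-positive intensity
  swapped <- compute_ma(dplyr::rename(df, fa_R = fa_G, fa_G = fa_R))
  expect_equal(swapped$M[1:2], -out$M[1:2])
  expect_equal(swapped$A[1:2], out$A[1:2])
})

test_that("M-A loess normalization removes an exact quadratic trend", {
  withr::with_seed(12, a <- sort(runif(300, 6, 16)))
  quad <- 0.5 - 0.2 * a + 0.01 * a^2
  prof <- tibble::tibble(feature_id = sprintf("f%03d", 1:300),
                         M = quad, A = a)
  out <- normalize_loess_ma(prof)
  expect_lt(max(abs(out$M)), 1e-6)
  zero <- normalize_loess_ma(dplyr::mutate(prof, M = 0))
  expect_equal(zero$M, rep(0, 300))
})

test_that("normalization shrinks an injected bias and is idempotent to tolerance", {
  withr::with_seed(13, {
    a <- runif(400, 6, 16)
    m <- (1 - 0.15 * a + 0.012 * a^2) + rnorm(400, 0, 0.1)
  })
  prof <- tibble::tibble(feature_id = sprintf("f%03d", 1:400), M = m, A = a)
  out <- normalize_loess_ma(prof)
  expect_lt(abs(median(out$M)), abs(median(prof$M)))
  # the residual trend of the normalized profile is flat
  refit <- stats::loess(M ~ A, data = out, span = 0.3, degree = 2)
  expect_lt(max(abs(fitted(refit))), 0.05)
  # a loess smoother is not a projection, so under noise a second pass can
  # still move points a little; it must move them far less than the first
  again <- normalize_loess_ma(out)
  expect_lt(max(abs(again$M - out$M)), 0.1 * max(abs(out$M - prof$M)))
})

test_that("normalization is idempotent to machine precision without noise", {
  withr::with_seed(18, a <- runif(300, 6, 16))
  prof <- tibble::tibble(feature_id = sprintf("f%03d", 1:300),
                         M = 2 - 0.4 * a + 0.02 * a^2, A = a)
  out <- normalize_loess_ma(prof)
  again <- normalize_loess_ma(out)
  expect_lt(max(abs(again$M - out$M)), 1e-3)
})

test_that("a too-small loess span is rejected with advice", {
  prof <- tibble::tibble(feature_id = sprintf("f%02d", 1:25),
                         M = rnorm(25), A = runif(25, 6, 16))
  expect_error(normalize_loess_ma(prof, span = 0.05), "larger span")
})

test_that("the loop filter keeps consistent features and flags discordant ones", {
  withr::with_seed(14, {
    n <- 200
    m1 <- rnorm(n)
    m2 <- rnorm(n)
  })
  ids <- sprintf("f%03d", 1:n)
  p <- function(m) tibble::tibble(feature_id = ids, M = m)
  consistent <- loop_design_filter(p(m1), p(m2), p(m1 + m2))
  expect_equal(consistent$ldf, rep(0, n))
  expect_true(all(consistent$keep))

  m3 <- m1 + m2 + withr::with_seed(15, rnorm(n, 0, 0.2))
  m3[17] <- m1[17] + m2[17] + 2 # a 10-sigma discordant feature
  res <- loop_design_filter(p(m1), p(m2), p(m3))
  expect_false(res$keep[17])
})

test_that("loop-filter retention under Gaussian discrepancy matches the 2 SD band", {
  n <- 20000
  withr::with_seed(16, {
    m1 <- rnorm(n); m2 <- rnorm(n); m3 <- m1 + m2 + rnorm(n, 0, 0.3)
  })
  ids <- sprintf("f%05d", 1:n)
  p <- function(m) tibble::tibble(feature_id = ids, M = m)
  res <- loop_design_filter(p(m1), p(m2), p(m3))
  expect_equal(mean(res$keep), 2 * pnorm(2) - 1, tolerance = 0.005)
})

test_that("loop filter demands a shared feature set and ignores feature order", {
  p1 <- tibble::tibble(feature_id = c("a", "b", "c"), M = c(1, 2, 3))
  p2 <- tibble::tibble(feature_id = c("a", "b", "d"), M = c(1, 2, 3))
  expect_error(loop_design_filter(p1, p1, p2), "d")
  withr::with_seed(17, {
    ids <- sprintf("f%02d", 1:30)
    q1 <- tibble::tibble(feature_id = ids, M = rnorm(30))
    q2 <- tibble::tibble(feature_id = ids, M = rnorm(30))
    q3 <- tibble::tibble(feature_id = ids, M = q1$M + q2$M + rnorm(30, 0, 0.1))
  })
  direct <- loop_design_filter(q1, q2, q3)
  shuffled <- loop_design_filter(q1[sample(30), ], q2[sample(30), ], q3)
  expect_equal(dplyr::arrange(shuffled, feature_id),
               dplyr::arrange(direct, feature_id), ignore_attr = TRUE)
})
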