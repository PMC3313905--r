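test_that("SD ranking matches direct computation and is deterministic", {
  withr::with_seed(41, {
    mat <- tibble::tibble(gene_id = sprintf("g%02d", 1:6),
                          `1` = rnorm(6), `2` = rnorm(6), `3` = rnorm(6))
  })
  top <- select_high_variance(mat, n = 3)
  sds <- apply(as.matrix(mat[-1]), 1, sd)
  expect_equal(top$gene_id, mat$gene_id[order(-sds, mat$gene_id)][1:3])
  expect_equal(select_high_variance(mat, n = 6)$gene_id,
               mat$gene_id[order(-sds, mat$gene_id)])
  expect_error(select_high_variance(mat, n = 7), "exceeds")

  flat <- mat
  flat[2:4] <- 0
  flat[1:5, 2] <- 1:5 # five genes with spread, the rest constant
  top5 <- select_high_variance(flat, n = 5)
  expect_setequal(top5$gene_id, flat$gene_id[1:5])
})

test_that("k-means recovers two planted blobs up to label permutation", {
  sim <- simulate_cluster_profiles(60, 4, k_true = 2, separation = 20,
                                   seed = 42)
  fit <- kmeans_best_of(sim$profiles, k = 2, n_init = 10, seed = 1)
  tab <- table(fit$assignment$cluster, sim$assignment$cluster)
  expect_equal(sum(apply(tab, 1, max)), 60) # pure clusters
  expect_equal(fit$within_sse, min(fit$restart_sse))
})

test_that("restarts can only improve the within-cluster SSE", {
  sim <- simulate_cluster_profiles(50, 3, k_true = 4, separation = 3,
                                   seed = 43)
  one <- kmeans_best_of(sim$profiles, k = 4, n_init = 1, seed = 5)
  many <- kmeans_best_of(sim$profiles, k = 4, n_init = 30, seed = 5)
  expect_lte(many$within_sse, one$within_sse)
})

test_that("silhouettes match a hand computation on four points", {
  mat <- matrix(c(0, 0, 0, 1, 10, 0, 10, 1), ncol = 2, byrow = TRUE,
                dimnames = list(paste0("p", 1:4), NULL))
  grp <- c(1, 1, 2, 2)
  sil <- silhouette_mean(mat, grp)
  # squared Euclidean: a = 1 for every point; b = (100 + 101)/2 = 100.5
  expect_equal(sil$silhouettes$silhouette, rep((100.5 - 1) / 100.5, 4))
  expect_equal(sil$mean_silhouette, (100.5 - 1) / 100.5)
})

test_that("silhouette conventions and invariances hold", {
  mat <- matrix(0, nrow = 6, ncol = 2,
                dimnames = list(paste0("p", 1:6), NULL))
  sil <- silhouette_mean(mat, c(1, 1, 1, 2, 2, 2))
  expect_equal(sil$silhouettes$silhouette, rep(0, 6)) # a = b = 0
  expect_error(silhouette_mean(mat, rep(1, 6)), "2 clusters")

  sim <- simulate_cluster_profiles(30, 3, k_true = 3, separation = 5,
                                   seed = 44)
  grp <- sim$assignment$cluster
  a <- silhouette_mean(sim$profiles, grp)
  b <- silhouette_mean(sim$profiles, 4 - grp) # relabelled
  expect_equal(a$silhouettes$silhouette, b$silhouettes$silhouette)
  expect_true(all(abs(a$silhouettes$silhouette) <= 1))
})

test_that("silhouette selection recovers the planted cluster number", {
  for (k_true in c(2, 7)) {
    sim <- simulate_cluster_profiles(80, 5, k_true = k_true,
                                     separation = 10, seed = 45 + k_true)
    sel <- select_optimal_k(sim$profiles, k_min = 2, k_max = 10,
                            n_init = 60, seed = 46 + k_true)
    expect_equal(sel$k_star, k_true)
    expect_equal(nrow(sel$curve), 9)
    expect_true(all(sel$curve$mean_silhouette >= -1 &
                      sel$curve$mean_silhouette <= 1))
  }
})

test_that("tidiers expose the fitted objects", {
  sim <- simulate_cluster_profiles(30, 3, k_true = 2, separation = 10,
                                   seed = 47)
  fit <- kmeans_best_of(sim$profiles, k = 2, n_init = 5, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("gene_id", "cluster", "silhouette"))
  expect_equal(nrow(td), 30)
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  sel <- select_optimal_k(sim$profiles, k_min = 2, k_max = 4,
                          n_init = 10, seed = 3)
  expect_equal(sum(tidy(sel)$optimal), 1L)
  expect_equal(glance(sel)$k_star, sel$k_star)
})
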