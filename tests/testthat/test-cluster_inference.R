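# Cluster inference: Hopkins null and clustered behaviour, consensus-k
# votes and recovery, WPGMA against a naive O(n^3) reference, PCA
# conventions, outlier flagging and BL/RL assignment contracts.

# samples-in-columns matrix from an n x p point cloud
points_as_matrix <- function(x) t(x)

test_that("Hopkins statistic is near 0.5 on uniform data", {
  vals <- vapply(1:100, function(s) {
    x <- withr::with_seed(1000 + s, matrix(runif(200 * 5), ncol = 5))
    hopkins_statistic(points_as_matrix(x), seed = s)
  }, numeric(1))
  expect_lt(abs(mean(1 - vals) - 0.5), 0.05)
})

test_that("Hopkins detects two well-separated clusters and degenerate piles", {
  vals <- vapply(1:100, function(s) {
    x <- withr::with_seed(2000 + s, {
      rbind(matrix(rnorm(100 * 5, 0, 0.5), ncol = 5),
            matrix(rnorm(100 * 5, 10, 0.5), ncol = 5))
    })
    hopkins_statistic(points_as_matrix(x), seed = s)
  }, numeric(1))
  expect_lt(mean(1 - vals), 0.3)
  # all points at one location: real nearest-neighbour distances vanish
  pile <- matrix(5, nrow = 3, ncol = 20)
  pile[1, ] <- pile[1, ] + rep(c(0, 1e-9), 10)  # break exact PCA degeneracy
  h <- hopkins_statistic(pile, seed = 1)
  expect_gt(h, 0.99)
  expect_error(hopkins_statistic(matrix(1, 2, 2)), "3 samples")
})

test_that("bootstrapped clusterability is reproducible and reduces to one call", {
  cc <- small_config(seed = 19)
  em <- build_expression_matrix(generate_counts(cc)$counts,
                                generate_counts(cc)$gene_meta)
  a <- bootstrapped_clusterability(em$log2fpm, reps = 25, seed = 5)
  b <- bootstrapped_clusterability(em$log2fpm, reps = 25, seed = 5)
  expect_identical(a$mean_one_minus_h, b$mean_one_minus_h)
  one <- bootstrapped_clusterability(em$log2fpm, reps = 1, seed = 5)
  single <- 1 - hopkins_statistic(em$log2fpm,
                                  seed = substream_seed(5, "hopkins1"))
  expect_equal(one$mean_one_minus_h, single)
  # the default two-archetype cohort is declared clusterable
  full <- bootstrapped_clusterability(em$log2fpm, reps = 64, seed = 5)
  expect_true(full$clusterable)
})

test_that("WPGMA reproduces the hand-computed 3-point merge history", {
  # 1-D embedding with d(A,B)=1, d(A,C)=4, d(B,C)=5; after merging (A,B) at
  # height 1 the WPGMA update gives d(AB,C) = (4+5)/2 = 4.5
  mat <- matrix(c(0, 1, -4), nrow = 1,
                dimnames = list("g1", c("A", "B", "C")))
  res <- wpgma_cluster(mat, k = 2)
  expect_equal(res$heights, c(1, 4.5))
  expect_identical(unname(res$labels[c("A", "B")]), c(1L, 1L))
  expect_false(res$labels[["C"]] == res$labels[["A"]])
  # k = n gives singletons; k > n errors
  expect_identical(length(unique(wpgma_cluster(mat, 3)$labels)), 3L)
  expect_error(wpgma_cluster(mat, 4), "exceeds")
})

test_that("WPGMA agrees with the naive O(n^3) reference on random instances", {
  n_trials <- 1000
  mismatches <- 0
  for (trial in seq_len(n_trials)) {
    x <- withr::with_seed(trial, matrix(rnorm(10 * 3), ncol = 3))
    mat <- points_as_matrix(x)
    colnames(mat) <- sprintf("P%02d", 1:10)
    ref <- naive_wpgma(as.matrix(dist(x)))
    got <- wpgma_cluster(mat, k = 2)
    if (!isTRUE(all.equal(sort(got$heights), sort(ref$heights),
                          tolerance = 1e-9)))
      mismatches <- mismatches + 1
    for (k in c(2, 4, 7)) {
      labs <- cutree(got$tree, k)
      if (!same_partition(labs, ref$partitions[[k]]))
        mismatches <- mismatches + 1
    }
    # merge heights are non-decreasing (no inversions)
    if (is.unsorted(got$heights)) mismatches <- mismatches + 1
  }
  expect_identical(mismatches, 0)
})

test_that("consensus votes are conserved and ties break toward smaller k", {
  cc <- small_config(seed = 23)
  co <- generate_counts(cc)
  em <- build_expression_matrix(co$counts, co$gene_meta)
  res <- consensus_cluster_number(em$log2fpm, reps = 15, seed = 3)
  expect_identical(sum(res$per_k_votes) + res$n_invalid,
                   res$n_evaluations)
  expect_identical(res$n_evaluations, 15L * 10L)
  # forced vote: single index, k_range of one value
  forced <- consensus_cluster_number(em$log2fpm, k_range = 2,
                                     indices = "calinski_harabasz",
                                     reps = 1, seed = 3)
  expect_identical(forced$chosen_k, 2L)
  expect_error(consensus_cluster_number(em$log2fpm, k_range = 1:4, seed = 1),
               "k_range")
  expect_error(consensus_cluster_number(em$log2fpm, indices = character(0),
                                        reps = 1, seed = 1), "non-empty")
})

test_that("consensus recovers a planted k = 3", {
  # three archetypes separated across every dimension, so any gene
  # subsample carries the structure
  x <- withr::with_seed(77, {
    do.call(rbind, lapply(c(0, 8, 16), function(mu)
      matrix(rnorm(15 * 40, mean = mu, sd = 1), nrow = 15)))
  })
  mat <- points_as_matrix(x)
  colnames(mat) <- sprintf("P%02d", 1:45)
  res <- consensus_cluster_number(mat, k_range = 2:6, reps = 20,
                                  gene_fraction = 0.5, seed = 4)
  expect_identical(res$chosen_k, 3L)
})

test_that("PCA projection fixes signs, orders variance and handles degeneracy", {
  x <- withr::with_seed(41, matrix(rnorm(30 * 8), ncol = 8))
  x[1:15, 1] <- x[1:15, 1] + 8
  mat <- points_as_matrix(x)
  colnames(mat) <- sprintf("P%02d", 1:30)
  coords <- pca_project(mat)
  expect_gte(var(coords[, 1]), var(coords[, 2]))
  # PC1 separates the two planted groups: silhouette above 0.5
  sil <- cluster::silhouette(rep(1:2, each = 15),
                             dist(coords[, 1, drop = FALSE]))
  expect_gt(mean(sil[, 3]), 0.5)
  # identical samples project to the origin
  same <- matrix(3, nrow = 5, ncol = 4,
                 dimnames = list(NULL, sprintf("P%d", 1:4)))
  expect_equal(unname(pca_project(same)), matrix(0, 4, 2))
  expect_error(pca_project(mat[, 1, drop = FALSE]), "2 samples")
  expect_error(pca_project(mat, n_components = 50), "rank")
})

test_that("outlier flagging ignores homogeneous clouds and catches displacement", {
  # expression-like dimensionality: mean-distance spread concentrates, so
  # false flags on a homogeneous cloud are rare
  none_flagged <- vapply(1:100, function(s) {
    x <- withr::with_seed(3000 + s, matrix(rnorm(30 * 200), ncol = 200))
    mat <- points_as_matrix(x)
    colnames(mat) <- sprintf("P%02d", 1:30)
    length(flag_outliers(mat)) == 0
  }, logical(1))
  expect_gte(mean(none_flagged), 0.95)
  x <- withr::with_seed(91, matrix(rnorm(30 * 10), ncol = 10))
  x[7, ] <- x[7, ] + 20  # displaced by 20 SD
  mat <- points_as_matrix(x)
  colnames(mat) <- sprintf("P%02d", 1:30)
  expect_identical(flag_outliers(mat), "P07")
  # identical samples: no outliers; minimum cohort size enforced
  same <- matrix(1, 3, 4, dimnames = list(NULL, sprintf("P%d", 1:4)))
  expect_identical(flag_outliers(same), character(0))
  expect_error(flag_outliers(same[, 1:3]), "4 samples")
})

test_that("negative samples inherit their cluster's driver majority", {
  labels <- c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L, S5 = 2L, S6 = 2L)
  status <- c(S1 = "positive-BRAF", S2 = "positive-BRAF", S3 = "negative",
              S4 = "negative", S5 = "positive-RAS", S6 = "positive-RAS")
  out <- assign_negative_classes(labels, status)
  expect_identical(out, c(S3 = "negative-BL", S4 = "negative-BL"))
  # PAX8-PPARg counts toward the RAS type
  status2 <- status
  status2[c("S1", "S2")] <- c("positive-PAX8-PPARg", "positive-RAS")
  status2["S5"] <- "negative"
  out2 <- assign_negative_classes(labels, status2)
  expect_identical(unname(out2[c("S3", "S4")]),
                   c("negative-RL", "negative-RL"))
  # cluster of positives only contributes nothing
  expect_identical(out[names(out) %in% c("S5", "S6")],
                   setNames(character(0), character(0)))
})

test_that("unresolved clusters error instead of guessing", {
  labels <- c(S1 = 1L, S2 = 1L, S3 = 2L, S4 = 2L, S5 = 2L)
  status <- c(S1 = "positive-BRAF", S2 = "negative", S3 = "positive-BRAF",
              S4 = "positive-RAS", S5 = "negative")
  expect_error(assign_negative_classes(labels, status), "tied.*S5")
  status2 <- c(S1 = "negative", S2 = "negative", S3 = "positive-RAS",
               S4 = "positive-RAS", S5 = "negative")
  expect_error(assign_negative_classes(labels, status2),
               "no driver-positive.*S1, S2")
  # flagged histology reroutes negatives before majority resolution
  hist <- c(S1 = "HCC", S2 = "HCC", S3 = NA, S4 = NA, S5 = "PTC")
  out <- assign_negative_classes(labels, status2, histology = hist)
  expect_identical(out[c("S1", "S2")],
                   c(S1 = "negative-other", S2 = "negative-other"))
  expect_identical(unname(out["S5"]), "negative-RL")
})
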