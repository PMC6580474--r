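# cohort with clean group structure, standardized, truth attached
grouped_std <- function(seed, n_met = 60, sep = 10, groups = 3) {
  spec <- quiet_spec(n_metabolites = n_met, n_profile_groups = groups,
                     profile_separation = sep, rng_seed = seed)
  co <- generate_cohort(spec)
  list(std = zscore_standardize(log_transform(co$cohort)),
       truth = co$truth)
}

test_that("k = 1 puts everything in one cluster with total-SS inertia", {
  g <- grouped_std(1, n_met = 20)
  cl <- kmeans_partition(g$std, k = 1, seed = 1)
  expect_true(all(cl$assignment == 1L))
  expect_length(cl$assignment, nrow(g$std$values))
  centered <- sweep(g$std$values, 2, colMeans(g$std$values))
  expect_equal(cl$inertia, sum(centered^2), tolerance = 1e-8)
})

test_that("well-separated planted groups are recovered exactly", {
  g <- grouped_std(2)
  cl <- kmeans_partition(g$std, k = 3, seed = 5)
  grp <- g$truth$profile_group_of_feature[names(cl$assignment)]
  expect_equal(mclust::adjustedRandIndex(cl$assignment, grp), 1)
})

test_that("inertia is non-increasing in k and k > n errors", {
  g <- grouped_std(3, n_met = 30)
  inertias <- sapply(1:5, function(k)
    kmeans_partition(g$std, k = k, seed = 9)$inertia)
  expect_true(all(diff(inertias) <= 1e-8))
  expect_error(kmeans_partition(g$std, k = 31, seed = 1), "exceeds")
})

test_that("PCA projection reports valid variance fractions and preserves geometry", {
  g <- grouped_std(4, n_met = 25)
  pc <- pca_project(g$std, n_components = 2)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  # full-rank projection is a rotation of the (column-centered) rows:
  # pairwise feature distances are preserved
  full <- pca_project(g$std, n_components = min(dim(g$std$values)))
  expect_equal(as.matrix(dist(full$coords)),
               as.matrix(dist(g$std$values)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 data: one component carries all the variance
  line <- make_fm(outer(c(1, 2, 5, -3), c(1, 0.5, 2)),
                  n_control = 2)
  pc1 <- pca_project(line, n_components = 2)
  expect_equal(pc1$var_explained[1], 1, tolerance = 1e-12)
})

test_that("a near-perfect classifier feature is ranked first", {
  hits <- 0L
  for (seed in 1:30) {
    set.seed(seed + 4000)
    n <- 23
    cls <- rep(c(0, 1), c(12, 11))
    x <- matrix(rnorm(100 * n), nrow = 100)
    x[1, ] <- cls + rnorm(n, sd = 0.01)
    rownames(x) <- sprintf("f%03d", 1:100)
    fm <- make_fm(x, n_control = 12)
    cl <- kmeans_partition(fm, k = 1, seed = seed)
    panel <- rf_rank(fm, cl, 1, n_trees = 500, seed = seed)
    if (panel$feature_id[1] == "f001") hits <- hits + 1L
    expect_true(all(panel$importance >= 0))
    expect_true(all(diff(panel$importance) <= 0))
  }
  expect_gte(hits, 28L)
})

test_that("permuting condition labels destroys the planted top rank", {
  hits <- 0L
  n_seeds <- 60L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed + 8000)
    n <- 23
    cls <- rep(c(0, 1), c(12, 11))
    x <- matrix(rnorm(30 * n), nrow = 30)
    x[1, ] <- cls + rnorm(n, sd = 0.01)
    rownames(x) <- sprintf("f%03d", 1:30)
    perm <- sample(n)   # break the feature-label link
    x <- x[, perm]
    colnames(x) <- NULL
    fm <- make_fm(x, n_control = 12)
    cl <- kmeans_partition(fm, k = 1, seed = seed)
    panel <- rf_rank(fm, cl, 1, n_trees = 300, seed = seed)
    if (panel$feature_id[1] == "f001") hits <- hits + 1L
  }
  expect_lte(hits / n_seeds, 0.10)
})

test_that("pure-noise clusters show no consistent separation", {
  oob <- sapply(1:60, function(seed) {
    set.seed(seed + 12000)
    x <- matrix(rnorm(40 * 23), nrow = 40,
                dimnames = list(sprintf("f%03d", 1:40), NULL))
    fm <- make_fm(x, n_control = 12)
    cl <- kmeans_partition(fm, k = 1, seed = seed)
    attr(rf_rank(fm, cl, 1, n_trees = 300, seed = seed), "oob_accuracy")
  })
  # no consistent class separation: OOB accuracy hovers around chance,
  # with at most occasional excursions outside a generous band
  expect_gte(mean(oob >= 0.2 & oob <= 0.8), 0.9)
  expect_gt(mean(oob), 0.25)
  expect_lt(mean(oob), 0.75)
})

test_that("top_n clamps, preserves order, and rf_rank breaks ties by id", {
  panel <- structure(
    data.frame(rank = 1:4,
               feature_id = c("a", "b", "c", "d"),
               importance = c(4, 3, 2, 1)),
    class = c("importance_panel", "data.frame"))
  expect_identical(top_n(panel, 2), c("a", "b"))
  expect_identical(top_n(panel, 29), c("a", "b", "c", "d"))
  # two identical predictor columns receive identical importance; the
  # lexicographically smaller id must come first
  set.seed(99)
  n <- 20
  cls <- rep(c(0, 1), each = 10)
  base <- cls + rnorm(n, sd = 0.3)
  x <- rbind(zz = base, aa = base, noise = rnorm(n))
  fm <- make_fm(x, n_control = 10)
  cl <- kmeans_partition(fm, k = 1, seed = 1)
  p <- rf_rank(fm, cl, 1, n_trees = 200, seed = 1)
  tied <- p$feature_id[p$importance == max(p$importance)]
  if (length(tied) > 1) expect_identical(tied, sort(tied))
})

test_that("feature-order permutation leaves clusters and top panels stable", {
  g <- grouped_std(6, n_met = 40, sep = 10)
  perm <- sample(nrow(g$std$values))
  permuted <- feature_matrix(g$std$values[perm, ],
                             g$std$kind[perm], g$std$condition)
  cl1 <- kmeans_partition(g$std, k = 3, seed = 7)
  cl2 <- kmeans_partition(permuted, k = 3, seed = 7)
  common <- names(cl1$assignment)
  expect_equal(mclust::adjustedRandIndex(cl1$assignment[common],
                                         cl2$assignment[common]), 1)
})

test_that("single-condition input is rejected", {
  x <- matrix(rnorm(10 * 6), nrow = 10,
              dimnames = list(sprintf("f%02d", 1:10),
                              sprintf("s%d", 1:6)))
  fm <- feature_matrix(x, setNames(rep("gene", 10), rownames(x)),
                       setNames(rep("control", 6), colnames(x)))
  cl <- kmeans_partition(fm, k = 1, seed = 1)
  expect_error(rf_rank(fm, cl, 1, n_trees = 100, seed = 1),
               "both conditions")
})
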