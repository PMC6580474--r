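#' Partition features with k-means
#'
#' Groups standardized biomolecule rows (features are the points, samples
#' the dimensions) into `k` clusters before random-forest ranking, so that
#' features from one expression profile cannot crowd out features showing
#' another pattern. Uses Euclidean k-means with `n_restarts` random starts
#' and keeps the best solution by total within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param m a standardized [feature_matrix()] (see [zscore_standardize()]).
#' @param k number of clusters (default 3).
#' @param seed integer RNG seed.
#' @param n_restarts number of random restarts (default 50).
#' @return an object of class `cluster_model`: list with `k`, `assignment`
#'   (named integer, feature id -> cluster in 1..k), `centroids`, `inertia`,
#'   `seed`, `n_restarts`.
#' @export
kmeans_partition <- function(m, k = 3, seed = 1L, n_restarts = 50L) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- m$values
  if (anyNA(x)) stop("k-means requires complete values; impute first")
  if (k > nrow(x)) stop("k (", k, ") exceeds number of features (",
                        nrow(x), ")")
  set.seed(substream_seed(seed, "kmeans"))
  km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100L)
  if (any(km$size == 0L)) stop("k-means produced an empty cluster")
  structure(
    list(k = k,
         assignment = stats::setNames(as.integer(km$cluster), rownames(x)),
         centroids = km$centers,
         inertia = km$tot.withinss,
         seed = as.integer(seed),
         n_restarts = as.integer(n_restarts)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, "| sizes:",
      paste(table(x$assignment), collapse = ", "),
      "| inertia:", format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' Project features onto leading principal components
#'
#' Features (rows) are the observations; samples are the original axes. The
#' sample-space is centered and the features are projected onto the leading
#' principal components, e.g. to display k-means clusters in PC-space.
#'
#' @param m a standardized [feature_matrix()].
#' @param n_components number of components to keep (default 2).
#' @return a list with `coords` (features x components matrix, columns
#'   `PC1`, `PC2`, ...) and `var_explained` (fraction of total variance per
#'   retained component, non-increasing).
#' @export
pca_project <- function(m, n_components = 2) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- m$values
  if (anyNA(x)) stop("PCA requires complete values")
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(features, samples)")
  if (all(abs(sweep(x, 2L, colMeans(x))) < 1e-300))
    stop("degenerate (rank-0) matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}

#' Rank one cluster's features by random-forest Gini importance
#'
#' Grows a classification forest with samples as instances, the cluster's
#' features as predictors and the control/treatment condition as the class,
#' then ranks the features by mean decrease in Gini impurity. The panel is
#' sorted by descending importance (ties broken by feature id) and carries
#' the out-of-bag accuracy as a gauge of how much condition signal the
#' cluster holds.
#'
#' @param m a standardized [feature_matrix()].
#' @param cluster a [kmeans_partition()] model.
#' @param cluster_index which cluster (1..k) to rank.
#' @param n_trees number of trees (default 10000; small cohorts need many
#'   trees for stable importances).
#' @param seed integer RNG seed.
#' @return an object of class `importance_panel`: data.frame with columns
#'   `rank`, `feature_id`, `importance`, plus attributes `cluster_index`,
#'   `n_trees`, `seed`, `oob_accuracy`.
#' @export
rf_rank <- function(m, cluster, cluster_index, n_trees = 10000L, seed = 1L) {
  stopifnot(inherits(m, "feature_matrix"),
            inherits(cluster, "cluster_model"))
  cond <- factor(m$condition, levels = c("control", "treatment"))
  if (nlevels(droplevels(cond)) < 2L)
    stop("both conditions must be present to rank by classifying power")
  ids <- names(cluster$assignment)[cluster$assignment == cluster_index]
  if (!length(ids)) stop("cluster ", cluster_index, " is empty")
  x <- t(m$values[ids, , drop = FALSE])
  set.seed(substream_seed(seed, paste0("rf", cluster_index)))
  fit <- randomForest::randomForest(x = x, y = cond, ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  panel <- data.frame(rank = seq_along(ids),
                      feature_id = names(imp)[ord],
                      importance = unname(imp[ord]),
                      stringsAsFactors = FALSE)
  structure(panel,
            class = c("importance_panel", "data.frame"),
            cluster_index = cluster_index,
            n_trees = as.integer(n_trees),
            seed = as.integer(seed),
            oob_accuracy = 1 - unname(fit$err.rate[n_trees, "OOB"]))
}

#' Take the top-ranked features from an importance panel
#'
#' @param panel an [rf_rank()] panel (sorted descending by importance with
#'   ties already broken by feature id).
#' @param n how many features to keep (default 29); clamped to the panel
#'   size.
#' @return character vector of feature ids in rank order.
#' @export
top_n <- function(panel, n = 29) {
  stopifnot(inherits(panel, "importance_panel") || is.data.frame(panel))
  utils::head(panel$feature_id, n)
}
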