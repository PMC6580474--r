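#' Hierarchically cluster prioritized biomolecules
#'
#' Agglomerative clustering of feature rows, used to organize the
#' top-ranked biomolecules into groups with similar measurement patterns
#' across samples. Distances are Euclidean on the standardized rows or
#' correlation distance (1 - Pearson r); linkage is one of average,
#' complete, single or Ward. Exact distance ties are resolved by the input
#' feature order, so runs are reproducible for a fixed input order.
#'
#' @param m a standardized [feature_matrix()], typically restricted with
#'   [subset_features()] to a prioritized panel.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"`, `"single"` or `"ward"`
#'   (Ward.D2 on Euclidean distances).
#' @return an object of class `feature_dendrogram`: list with `hclust` (the
#'   stats::hclust fit), `leaves` (feature ids), `metric`, `linkage`.
#' @export
hclust_features <- function(m, metric = c("euclidean", "correlation"),
                            linkage = c("average", "complete", "single",
                                        "ward")) {
  stopifnot(inherits(m, "feature_matrix"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (nrow(m$values) < 2L)
    stop("need at least 2 features to build a dendrogram")
  if (anyNA(m$values)) stop("dendrogram requires complete values")
  d <- switch(metric,
    euclidean = stats::dist(m$values),
    correlation = stats::as.dist(1 - stats::cor(t(m$values))))
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, leaves = rownames(m$values),
                 metric = metric, linkage = linkage),
            class = "feature_dendrogram")
}

#' @export
print.feature_dendrogram <- function(x, ...) {
  cat("feature_dendrogram:", length(x$leaves), "leaves |", x$metric,
      "distance,", x$linkage, "linkage\n")
  invisible(x)
}

#' Cut a dendrogram into a fixed number of groups
#'
#' @param d a [hclust_features()] dendrogram.
#' @param n_groups number of groups, between 1 and the number of leaves.
#' @return named integer vector mapping feature id to group index.
#' @export
cut_groups <- function(d, n_groups) {
  stopifnot(inherits(d, "feature_dendrogram"))
  n_leaves <- length(d$leaves)
  if (n_groups < 1L || n_groups > n_leaves)
    stop("n_groups must be between 1 and ", n_leaves)
  stats::cutree(d$hclust, k = n_groups)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: each child branch has
#' length equal to its parent's merge height minus the child's own height
#' (leaves sit at height 0), so leaf-to-root path length equals the root
#' merge height.
#'
#' @param d a [hclust_features()] dendrogram.
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(d) {
  stopifnot(inherits(d, "feature_dendrogram"))
  hc <- d$hclust
  node_str <- function(node, parent_height) {
    if (node < 0) {  # negative entries index leaves in hclust's merge table
      sprintf("%s:%.10g", hc$labels[-node], parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%.10g",
              node_str(hc$merge[node, 1L], h),
              node_str(hc$merge[node, 2L], h),
              parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);",
          node_str(hc$merge[root, 1L], h),
          node_str(hc$merge[root, 2L], h))
}

#' Cophenetic distances of a dendrogram
#'
#' Distance between two leaves is the merge height at which they first join
#' one cluster; for single/complete/average linkage this is an ultrametric.
#'
#' @param d a [hclust_features()] dendrogram.
#' @return a `dist` object over the leaves.
#' @export
cophenetic_distances <- function(d) {
  stopifnot(inherits(d, "feature_dendrogram"))
  stats::cophenetic(d$hclust)
}
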