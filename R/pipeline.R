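#' Configuration for the end-to-end pipeline
#'
#' Bundles the file paths and every tunable of the workflow: enrichment
#' threshold (z > 5), k-means k (3), trees and panel size of the
#' random-forest ranking (top 29), hierarchical-clustering metric/linkage,
#' fork roles and the fork significance level (0.05). Defaults match the
#' study settings the package emulates. A config round-trips losslessly
#' through its YAML file form via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param compendium_path,tissue_path compendium matrix and library->tissue
#'   CSVs (see [read_compendium()]).
#' @param matrix_path,condition_path joint cohort matrix and
#'   sample->condition CSVs (see [read_feature_matrix()]).
#' @param tissue target tissue label for enrichment.
#' @param z_threshold enrichment cutoff (strict `z > threshold`).
#' @param k number of k-means clusters.
#' @param n_trees random-forest trees per cluster.
#' @param top_n panel size per cluster.
#' @param hclust_metric,hclust_linkage see [hclust_features()].
#' @param fork_roles optional list with character elements `A`, `B`, `C`
#'   naming candidate metabolites per role; `NULL` uses the prioritized
#'   metabolites (union over cluster panels) in every role.
#' @param alpha fork raw-p significance level.
#' @param adjust `"benjamini-hochberg"` or `"none"`.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir directory receiving all artifacts.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(compendium_path, tissue_path, matrix_path,
                            condition_path, out_dir, tissue = "liver",
                            z_threshold = 5, k = 3, n_trees = 10000,
                            top_n = 29, hclust_metric = "euclidean",
                            hclust_linkage = "average", fork_roles = NULL,
                            alpha = 0.05, adjust = "benjamini-hochberg",
                            seed = 1L) {
  structure(list(compendium_path = compendium_path,
                 tissue_path = tissue_path,
                 matrix_path = matrix_path,
                 condition_path = condition_path,
                 out_dir = out_dir, tissue = tissue,
                 z_threshold = z_threshold, k = k, n_trees = n_trees,
                 top_n = top_n, hclust_metric = hclust_metric,
                 hclust_linkage = hclust_linkage, fork_roles = fork_roles,
                 alpha = alpha, adjust = adjust, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Join gene and metabolite matrices on shared samples
#'
#' Transcriptome and metabolome cohorts rarely profile identical sample
#' sets; joint feature vectors need complete columns, so the default keeps
#' the intersection of sample ids. Union mode keeps every sample and
#' carries missing gene values for samples absent from the gene matrix
#' (genes become NA-bearing, so union output is for inspection, not for
#' standardization).
#'
#' @param gene_m,metab_m [feature_matrix()] objects (kinds need not be
#'   pure; rows are concatenated as-is).
#' @param mode `"intersection"` (default) or `"union"`.
#' @return the joined `feature_matrix`.
#' @export
reconcile_samples <- function(gene_m, metab_m,
                              mode = c("intersection", "union")) {
  stopifnot(inherits(gene_m, "feature_matrix"),
            inherits(metab_m, "feature_matrix"))
  mode <- match.arg(mode)
  g_s <- colnames(gene_m$values)
  m_s <- colnames(metab_m$values)
  shared <- intersect(g_s, m_s)
  if (!length(shared))
    stop("gene and metabolite matrices share no sample ids")
  dup <- intersect(rownames(gene_m$values), rownames(metab_m$values))
  if (length(dup)) stop("duplicate feature id across matrices: ", dup[1L])
  samples <- if (mode == "intersection") shared else union(g_s, m_s)
  take <- function(m, samples) {
    out <- matrix(NA_real_, nrow(m$values), length(samples),
                  dimnames = list(rownames(m$values), samples))
    have <- intersect(samples, colnames(m$values))
    out[, have] <- m$values[, have]
    out
  }
  vals <- rbind(take(gene_m, samples), take(metab_m, samples))
  kind <- c(gene_m$kind, metab_m$kind)
  condition <- c(gene_m$condition, metab_m$condition)
  condition <- condition[!duplicated(names(condition))]
  feature_matrix(vals, kind, condition,
                 allow_missing_genes = mode == "union")
}

#' Run the full prioritization + fork-screening pipeline
#'
#' Executes, in order: tissue-enrichment subsetting of genes against the
#' compendium; restriction of the joint cohort to enriched genes plus all
#' metabolites; minimum-value imputation, log transform and z-score
#' standardization; k-means partitioning; per-cluster random-forest ranking
#' and top-N panels; per-cluster hierarchical clustering of the panel;
#' Welch tests per feature; and the metabolic-fork screen over the
#' configured (or prioritized-metabolite) roles. All artifacts are written
#' under `cfg$out_dir`; the run is fully reproducible given config + seed.
#'
#' Fork ratios use post-imputation raw abundances over the metabolome's
#' full sample set, while clustering/ranking run on the standardized joint
#' matrix.
#'
#' @param cfg a [pipeline_config()].
#' @return a `run_report` list: per-stage dimensions, dropped-feature log,
#'   enriched-gene count, cluster sizes, per-cluster out-of-bag accuracy,
#'   significant-fork count, seeds and stage order; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(stages = character(), seeds = list(seed = cfg$seed),
                 dropped = list())

  comp <- stage("read-compendium",
                read_compendium(cfg$compendium_path, cfg$tissue_path))
  scores <- stage("enrichment",
                  enrichment_z(comp, cfg$tissue, threshold = cfg$z_threshold))
  enriched <- filter_enriched(scores, threshold = cfg$z_threshold)
  utils::write.csv(scores, file.path(cfg$out_dir, "enrichment_scores.csv"),
                   row.names = FALSE)
  writeLines(enriched, file.path(cfg$out_dir, "enriched_genes.txt"))
  report$stages <- c(report$stages, "enrichment")
  report$enriched_gene_count <- length(enriched)

  cohort <- stage("read-cohort",
                  read_feature_matrix(cfg$matrix_path, cfg$condition_path))
  report$cohort_dim <- dim(cohort$values)
  keep <- c(intersect(enriched, rownames(cohort$values)[cohort$kind == "gene"]),
            rownames(cohort$values)[cohort$kind == "metabolite"])
  joint <- stage("subset", subset_features(cohort, features = keep))
  report$stages <- c(report$stages, "subset")
  report$joint_dim <- dim(joint$values)

  imputed <- stage("preprocess", withCallingHandlers(
    impute_min(joint),
    warning = function(w) {
      report$dropped$impute <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }))
  std <- stage("preprocess", withCallingHandlers(
    zscore_standardize(log_transform(imputed)),
    warning = function(w) {
      report$dropped$standardize <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }))
  report$stages <- c(report$stages, "preprocess")
  report$standardized_dim <- dim(std$values)

  welch <- stage("welch", suppressWarnings(welch_test(std)))
  utils::write.csv(welch, file.path(cfg$out_dir, "welch_tests.csv"),
                   row.names = FALSE)
  report$stages <- c(report$stages, "welch")

  cl <- stage("kmeans", kmeans_partition(std, k = cfg$k, seed = cfg$seed))
  utils::write.csv(data.frame(feature_id = names(cl$assignment),
                              cluster = unname(cl$assignment)),
                   file.path(cfg$out_dir, "cluster_assignment.csv"),
                   row.names = FALSE)
  pc <- stage("pca", pca_project(std, n_components = 2))
  utils::write.csv(data.frame(feature_id = rownames(pc$coords), pc$coords),
                   file.path(cfg$out_dir, "pc_coordinates.csv"),
                   row.names = FALSE)
  report$stages <- c(report$stages, "kmeans", "pca")
  report$cluster_sizes <- as.integer(table(cl$assignment))

  panels <- list()
  report$oob_accuracy <- numeric(cfg$k)
  for (ci in seq_len(cfg$k)) {
    panel <- stage("rf-rank",
                   rf_rank(std, cl, ci, n_trees = cfg$n_trees,
                           seed = cfg$seed))
    utils::write.csv(as.data.frame(panel),
                     file.path(cfg$out_dir,
                               sprintf("importance_cluster%d.csv", ci)),
                     row.names = FALSE)
    panels[[ci]] <- top_n(panel, cfg$top_n)
    report$oob_accuracy[ci] <- attr(panel, "oob_accuracy")
    if (length(panels[[ci]]) >= 2L) {
      dd <- stage("dendro",
                  hclust_features(subset_features(std, panels[[ci]]),
                                  metric = cfg$hclust_metric,
                                  linkage = cfg$hclust_linkage))
      writeLines(to_newick(dd),
                 file.path(cfg$out_dir, sprintf("dendrogram_cluster%d.nwk",
                                                ci)))
    }
  }
  report$stages <- c(report$stages, "rf-rank", "dendro")
  report$top_panels <- panels

  # fork screen: metabolites only, full metabolome sample set, raw scale
  met_ids <- rownames(cohort$values)[cohort$kind == "metabolite"]
  met_raw <- stage("forks", suppressWarnings(
    impute_min(subset_features(cohort, features = met_ids))))
  roles <- cfg$fork_roles
  if (is.null(roles)) {
    prioritized <- intersect(unique(unlist(panels)), met_ids)
    roles <- list(A = prioritized, B = prioritized, C = prioritized)
  }
  forks <- if (length(roles$A) && length(roles$B) && length(roles$C)) {
    trips <- stage("forks",
                   enumerate_triplets(roles$A, roles$B, roles$C))
    stage("forks", screen_forks(met_raw, trips, alpha = cfg$alpha,
                                adjust = cfg$adjust))
  } else {
    NULL
  }
  if (!is.null(forks))
    utils::write.csv(forks, file.path(cfg$out_dir, "fork_screen.csv"),
                     row.names = FALSE)
  report$stages <- c(report$stages, "forks")
  report$n_triplets <- if (is.null(forks)) 0L else nrow(forks)
  report$significant_fork_count <-
    if (is.null(forks)) 0L else sum(forks$significant)

  report <- structure(report, class = "run_report")
  jsonlite::write_json(unclass(report),
                       file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", paste(unique(x$stages), collapse = " -> "), "\n")
  cat("  enriched genes:", x$enriched_gene_count,
      "| joint matrix:", paste(x$joint_dim, collapse = " x "), "\n")
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "),
      "| OOB accuracy:",
      paste(format(x$oob_accuracy, digits = 3), collapse = ", "), "\n")
  cat("  triplets screened:", x$n_triplets,
      "| significant forks:", x$significant_fork_count, "\n")
  invisible(x)
}
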