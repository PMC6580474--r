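#' Joint biomolecule-by-sample matrix
#'
#' Container for a joint feature (gene + metabolite) by sample abundance
#' matrix with a condition label per sample. Genes and metabolites are both
#' treated as "biomolecules": rows of one matrix, distinguished only by their
#' `kind`. Missing values are permitted in metabolite rows only (metabolomics
#' platforms censor low-abundance compounds); gene rows must be complete.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Must carry unique rownames (feature ids) and colnames (sample ids).
#' @param kind named character vector mapping every feature id to `"gene"`
#'   or `"metabolite"`.
#' @param condition named character vector mapping every sample id to
#'   `"control"` or `"treatment"`.
#' @param allow_missing_genes permit NA in gene rows; only union-mode
#'   sample joins produce such matrices (see [reconcile_samples()]).
#' @return an object of class `feature_matrix`: a list with elements
#'   `values`, `kind` and `condition`, aligned to the matrix dimnames.
#' @export
feature_matrix <- function(values, kind, condition,
                           allow_missing_genes = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  missing_kind <- setdiff(fid, names(kind))
  if (length(missing_kind))
    stop("feature without kind: ", missing_kind[1L])
  kind <- kind[fid]
  if (!all(kind %in% c("gene", "metabolite")))
    stop("kind values must be 'gene' or 'metabolite'")
  missing_cond <- setdiff(sid, names(condition))
  if (length(missing_cond))
    stop("sample absent from condition map: ", missing_cond[1L])
  condition <- condition[sid]
  if (!all(condition %in% c("control", "treatment")))
    stop("condition values must be 'control' or 'treatment'")
  gene_rows <- values[kind == "gene", , drop = FALSE]
  if (!allow_missing_genes && anyNA(gene_rows))
    stop("missing values are only allowed in metabolite rows")
  structure(
    list(values = values, kind = kind, condition = condition),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  cat("  genes:", sum(x$kind == "gene"),
      " metabolites:", sum(x$kind == "metabolite"), "\n")
  cat("  control:", sum(x$condition == "control"),
      " treatment:", sum(x$condition == "treatment"), "\n")
  cat("  missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by feature and/or sample ids
#'
#' @param m a [feature_matrix()].
#' @param features,samples character vectors of ids to keep (default all).
#' @return a `feature_matrix` restricted to the requested rows/columns.
#' @export
subset_features <- function(m, features = rownames(m$values),
                            samples = colnames(m$values)) {
  stopifnot(inherits(m, "feature_matrix"))
  unknown <- setdiff(features, rownames(m$values))
  if (length(unknown)) stop("unknown feature id: ", unknown[1L])
  unknown <- setdiff(samples, colnames(m$values))
  if (length(unknown)) stop("unknown sample id: ", unknown[1L])
  feature_matrix(m$values[features, samples, drop = FALSE],
                 m$kind[features], m$condition[samples])
}

#' Read a feature matrix and its condition map from delimited text
#'
#' The matrix file is CSV with columns `feature_id`, `kind`, then one column
#' per sample; the condition file is CSV with columns `sample_id`,
#' `condition`. Empty cells and `NA` are read as missing.
#'
#' @param matrix_path path to the feature x sample CSV.
#' @param condition_path path to the sample condition CSV.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(matrix_path, condition_path) {
  tab <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!all(c("feature_id", "kind") %in% names(tab)[1:2]))
    stop("matrix file must start with columns 'feature_id' and 'kind'")
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature id: ", tab$feature_id[duplicated(tab$feature_id)][1L])
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab$feature_id
  kind <- stats::setNames(tab$kind, tab$feature_id)
  cond_tab <- utils::read.csv(condition_path, stringsAsFactors = FALSE)
  condition <- stats::setNames(cond_tab$condition, cond_tab$sample_id)
  feature_matrix(vals, kind, condition)
}

#' Write a feature matrix and its condition map as delimited text
#'
#' Inverse of [read_feature_matrix()]: missing entries are written as empty
#' cells.
#'
#' @param m a [feature_matrix()].
#' @param matrix_path,condition_path output CSV paths.
#' @return invisibly, `m`.
#' @export
write_feature_matrix <- function(m, matrix_path, condition_path) {
  stopifnot(inherits(m, "feature_matrix"))
  tab <- data.frame(feature_id = rownames(m$values),
                    kind = unname(m$kind),
                    m$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, matrix_path, row.names = FALSE, na = "")
  cond <- data.frame(sample_id = colnames(m$values),
                     condition = unname(m$condition))
  utils::write.csv(cond, condition_path, row.names = FALSE)
  invisible(m)
}

#' Impute missing metabolite values with the per-compound minimum
#'
#' Every missing entry in a metabolite row is replaced by that row's minimum
#' observed value; observed entries and gene rows are untouched. Rows with no
#' observed value at all cannot be imputed and are dropped with a warning.
#' The operation is idempotent.
#'
#' @param m a [feature_matrix()].
#' @return a `feature_matrix` with no missing values.
#' @export
impute_min <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing)) {
    warning("dropping all-missing feature row(s): ",
            paste(rownames(vals)[all_missing], collapse = ", "))
    vals <- vals[!all_missing, , drop = FALSE]
  }
  has_na <- which(rowSums(is.na(vals)) > 0L)
  for (i in has_na) {
    row <- vals[i, ]
    row[is.na(row)] <- min(row, na.rm = TRUE)
    vals[i, ] <- row
  }
  feature_matrix(vals, m$kind[rownames(vals)], m$condition)
}

#' Natural-log transform all abundances
#'
#' @param m a [feature_matrix()] with strictly positive, complete values
#'   (run [impute_min()] first).
#' @return the log-transformed `feature_matrix`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive value for feature '", rownames(m$values)[bad[1L, 1L]],
         "' in sample '", colnames(m$values)[bad[1L, 2L]], "'")
  }
  feature_matrix(log(m$values), m$kind, m$condition)
}

#' Welch's two-sample t-test per feature
#'
#' Compares control against treatment samples for every feature with the
#' unequal-variance (Welch) t-test and Welch-Satterthwaite degrees of
#' freedom. Features whose values are essentially constant in both groups
#' have no defined statistic; they are reported with missing `t`/`p` and a
#' warning.
#'
#' @param m a [feature_matrix()] (typically log-transformed).
#' @return a data.frame with columns `feature_id`, `t`, `df`, `p`,
#'   `mean_control`, `mean_treatment`.
#' @export
welch_test <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  ctl <- m$condition == "control"
  trt <- m$condition == "treatment"
  if (sum(ctl) < 2L || sum(trt) < 2L)
    stop("need at least 2 samples per condition")
  res <- lapply(rownames(m$values), function(fid) {
    x <- m$values[fid, ctl]
    y <- m$values[fid, trt]
    tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      warning("degenerate (constant) feature '", fid, "': p undefined")
      data.frame(feature_id = fid, t = NA_real_, df = NA_real_, p = NA_real_,
                 mean_control = mean(x, na.rm = TRUE),
                 mean_treatment = mean(y, na.rm = TRUE))
    } else {
      data.frame(feature_id = fid,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_control = mean(x, na.rm = TRUE),
                 mean_treatment = mean(y, na.rm = TRUE))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Z-score standardize every feature row
#'
#' Centers each row to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator), so genes and metabolites on very different scales
#' contribute comparably downstream. Constant rows have no defined z-score
#' and are dropped with a warning naming them.
#'
#' @param m a [feature_matrix()] with complete values.
#' @return the standardized `feature_matrix`.
#' @export
zscore_standardize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (anyNA(m$values))
    stop("standardization requires complete values; run impute_min() first")
  mu <- rowMeans(m$values)
  sd <- apply(m$values, 1L, stats::sd)
  constant <- sd == 0
  if (any(constant)) {
    warning("dropping constant feature row(s): ",
            paste(rownames(m$values)[constant], collapse = ", "))
  }
  keep <- !constant
  vals <- (m$values[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  feature_matrix(vals, m$kind[rownames(vals)], m$condition)
}
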