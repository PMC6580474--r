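#' Multi-tissue expression compendium
#'
#' A gene x library abundance matrix with a tissue label per library, used
#' as the background for tissue-enrichment scoring.
#'
#' @param values numeric matrix, genes in rows, libraries in columns, with
#'   unique rownames and colnames.
#' @param tissue named character vector mapping every library id to a
#'   tissue label.
#' @return an object of class `tissue_compendium`.
#' @export
tissue_compendium <- function(values, tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and library colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id")
  missing_tissue <- setdiff(colnames(values), names(tissue))
  if (length(missing_tissue))
    stop("library without tissue label: ", missing_tissue[1L])
  structure(list(values = values, tissue = tissue[colnames(values)]),
            class = "tissue_compendium")
}

#' @export
print.tissue_compendium <- function(x, ...) {
  cat("tissue_compendium:", nrow(x$values), "genes x", ncol(x$values),
      "libraries over", length(unique(x$tissue)), "tissues\n")
  invisible(x)
}

#' Read / write a compendium as delimited text
#'
#' The matrix file is CSV with a `gene_id` column then one column per
#' library; the companion file maps `library_id` to `tissue`.
#'
#' @param matrix_path,tissue_path CSV paths.
#' @return a [tissue_compendium()].
#' @export
read_compendium <- function(matrix_path, tissue_path) {
  tab <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab[[1L]]
  tt <- utils::read.csv(tissue_path, stringsAsFactors = FALSE)
  tissue_compendium(vals, stats::setNames(tt$tissue, tt$library_id))
}

#' @rdname read_compendium
#' @param comp a [tissue_compendium()].
#' @export
write_compendium <- function(comp, matrix_path, tissue_path) {
  stopifnot(inherits(comp, "tissue_compendium"))
  tab <- data.frame(gene_id = rownames(comp$values), comp$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, matrix_path, row.names = FALSE)
  utils::write.csv(data.frame(library_id = colnames(comp$values),
                              tissue = unname(comp$tissue)),
                   tissue_path, row.names = FALSE)
  invisible(comp)
}

#' Tissue-enrichment z-scores against a multi-tissue background
#'
#' For every gene, computes
#' `z = (mean over tissue-of-interest libraries - mean over background
#' libraries) / sd over background libraries`, with the sample (n - 1)
#' standard deviation. By default the background excludes the target
#' tissue's own libraries so the score is not self-contaminated; set
#' `include_target_in_background = TRUE` to score against all libraries.
#' Genes whose background sd is zero have no defined z; they are reported
#' with `z = NA`, `enriched = FALSE` and a warning.
#'
#' @param comp a [tissue_compendium()].
#' @param tissue target tissue label.
#' @param threshold enrichment calls use `z > threshold` (strict).
#' @param include_target_in_background logical; see above.
#' @return a data.frame with columns `gene_id`, `tissue_mean`,
#'   `background_mean`, `background_sd`, `z`, `enriched`.
#' @export
enrichment_z <- function(comp, tissue, threshold = 5,
                         include_target_in_background = FALSE) {
  stopifnot(inherits(comp, "tissue_compendium"))
  in_tissue <- comp$tissue == tissue
  if (!any(in_tissue))
    stop("tissue '", tissue, "' not present in compendium")
  bg <- if (include_target_in_background) rep(TRUE, ncol(comp$values))
        else !in_tissue
  if (sum(bg) < 2L)
    stop("need at least 2 background libraries")
  tissue_mean <- rowMeans(comp$values[, in_tissue, drop = FALSE])
  background_mean <- rowMeans(comp$values[, bg, drop = FALSE])
  background_sd <- apply(comp$values[, bg, drop = FALSE], 1L, stats::sd)
  z <- (tissue_mean - background_mean) / background_sd
  z[background_sd == 0] <- NA_real_
  if (anyNA(z))
    warning("background sd is zero for ", sum(is.na(z)),
            " gene(s); z undefined there")
  data.frame(gene_id = rownames(comp$values),
             tissue_mean = tissue_mean,
             background_mean = background_mean,
             background_sd = background_sd,
             z = z,
             enriched = !is.na(z) & z > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset genes passing the enrichment threshold
#'
#' @param scores output of [enrichment_z()].
#' @param threshold z cutoff; a gene is kept iff `z > threshold` (strict).
#' @return character vector of gene ids, ordered by descending z.
#' @export
filter_enriched <- function(scores, threshold = 5) {
  keep <- !is.na(scores$z) & scores$z > threshold
  sel <- scores[keep, , drop = FALSE]
  sel$gene_id[order(-sel$z, sel$gene_id)]
}
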