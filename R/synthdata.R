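#' Specification for the synthetic multi-omics generator
#'
#' Collects every knob the generator needs: cohort and compendium sizes,
#' planted effect sizes (all in units of the relevant noise standard
#' deviation), fork definitions and the missing-data rate. Defaults mirror
#' the study design the package emulates: 12 control and 11 heat-stress
#' metabolome samples, 3 latent expression-profile groups, and a strict
#' tissue-enrichment screen.
#'
#' @param n_genes,n_metabolites number of gene / metabolite features in the
#'   cohort (genes are also the compendium's rows).
#' @param n_background_libraries,n_tissue_libraries compendium libraries in
#'   the multi-tissue background and in the tissue of interest.
#' @param n_control_samples,n_treatment_samples cohort sizes per condition.
#' @param n_enriched_genes genes planted as tissue-enriched in the
#'   compendium.
#' @param enrichment_effect planted elevation of the tissue-library mean, in
#'   background-standard-deviation units.
#' @param n_profile_groups number of latent feature-profile groups; features
#'   in one group share a per-sample latent factor.
#' @param profile_separation loading on the shared group factor, in units of
#'   the per-feature noise sd (log scale); larger values separate the group
#'   centroids further apart in sample-space.
#' @param n_discriminative features planted with a condition mean shift.
#' @param discriminative_shift size of that shift, in units of the
#'   feature's marginal (group factor + noise) standard deviation on the
#'   log scale, so a 3-sd shift is detectable at any profile separation.
#' @param fork_specs list of fork definitions, each a list/vector with
#'   elements `slope_control`, `slope_treatment`, `noise_sd`; each fork
#'   plants one metabolite triplet (A, B, C) with A = slope * B/C + noise,
#'   slope depending on condition.
#' @param missing_rate probability that a metabolite value in the bottom
#'   quartile of its compound's distribution is censored to missing.
#' @param rng_seed integer seed; all stages draw from named substreams of it.
#' @return a validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, n_metabolites = 60,
                           n_background_libraries = 50,
                           n_tissue_libraries = 16,
                           n_control_samples = 12, n_treatment_samples = 11,
                           n_enriched_genes = 20, enrichment_effect = 8,
                           n_profile_groups = 3, profile_separation = 10,
                           n_discriminative = 10, discriminative_shift = 3,
                           fork_specs = list(), missing_rate = 0.1,
                           rng_seed = 1L) {
  spec <- structure(
    list(n_genes = n_genes, n_metabolites = n_metabolites,
         n_background_libraries = n_background_libraries,
         n_tissue_libraries = n_tissue_libraries,
         n_control_samples = n_control_samples,
         n_treatment_samples = n_treatment_samples,
         n_enriched_genes = n_enriched_genes,
         enrichment_effect = enrichment_effect,
         n_profile_groups = n_profile_groups,
         profile_separation = profile_separation,
         n_discriminative = n_discriminative,
         discriminative_shift = discriminative_shift,
         fork_specs = fork_specs, missing_rate = missing_rate,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  counts <- c("n_genes", "n_metabolites", "n_background_libraries",
              "n_tissue_libraries", "n_control_samples",
              "n_treatment_samples", "n_enriched_genes", "n_profile_groups",
              "n_discriminative")
  for (f in counts) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop("invalid synthetic_spec field `", f,
           "`: must be a single non-negative integer")
  }
  if (spec$n_enriched_genes > spec$n_genes)
    stop("invalid synthetic_spec field `n_enriched_genes`: exceeds n_genes")
  if (spec$n_discriminative > spec$n_genes + spec$n_metabolites)
    stop("invalid synthetic_spec field `n_discriminative`: ",
         "exceeds total feature count")
  if (!is.numeric(spec$missing_rate) || spec$missing_rate < 0 ||
      spec$missing_rate >= 1)
    stop("invalid synthetic_spec field `missing_rate`: must be in [0, 1)")
  if (3L * length(spec$fork_specs) > spec$n_metabolites)
    stop("invalid synthetic_spec field `fork_specs`: ",
         "forks require more metabolites than n_metabolites provides")
  for (fs in spec$fork_specs) {
    if (!all(c("slope_control", "slope_treatment", "noise_sd") %in%
             names(fs)))
      stop("invalid synthetic_spec field `fork_specs`: each fork needs ",
           "slope_control, slope_treatment and noise_sd")
  }
  if (is.na(spec$rng_seed))
    stop("invalid synthetic_spec field `rng_seed`")
  invisible(spec)
}

# One shared seed with a named substream per stage: regenerating one output
# (say the cohort) never perturbs another (the compendium).
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((abs(as.numeric(seed)) * 2654435L + h * 97L) %% 2147483647)
}

#' Generate a synthetic multi-tissue expression compendium
#'
#' Simulates a gene x library matrix containing `n_tissue_libraries` target
#' tissue ("liver") libraries and `n_background_libraries` libraries spread
#' over other tissues. Each gene has its own baseline mean and dispersion;
#' planted enriched genes have their tissue-library mean elevated by
#' `enrichment_effect` background standard deviations. Deterministic given
#' `rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `compendium` (a [tissue_compendium()]) and
#'   `truth` (the planted-ground-truth record; see details in
#'   [generate_cohort()]).
#' @export
generate_compendium <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(substream_seed(spec$rng_seed, "compendium"))
  n_lib <- spec$n_tissue_libraries + spec$n_background_libraries
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  lib_ids <- c(sprintf("liver_lib%03d", seq_len(spec$n_tissue_libraries)),
               sprintf("bg_lib%03d", seq_len(spec$n_background_libraries)))
  other_tissues <- c("breast", "brain", "kidney", "heart", "lung", "spleen")
  tissue <- stats::setNames(
    c(rep("liver", spec$n_tissue_libraries),
      rep_len(other_tissues, spec$n_background_libraries)),
    lib_ids)
  mu <- stats::runif(spec$n_genes, 4, 8)       # per-gene baseline (log2-ish)
  sigma <- stats::runif(spec$n_genes, 0.3, 0.6)
  vals <- matrix(stats::rnorm(spec$n_genes * n_lib, mean = mu, sd = sigma),
                 nrow = spec$n_genes, ncol = n_lib,
                 dimnames = list(gene_ids, lib_ids))
  enriched <- if (spec$n_enriched_genes > 0)
    sort(sample(gene_ids, spec$n_enriched_genes)) else character()
  if (length(enriched)) {
    idx <- match(enriched, gene_ids)
    tidx <- seq_len(spec$n_tissue_libraries)
    vals[idx, tidx] <- vals[idx, tidx] +
      spec$enrichment_effect * sigma[idx]
  }
  truth <- planted_truth(enriched_gene_ids = enriched)
  list(compendium = tissue_compendium(vals, tissue), truth = truth)
}

planted_truth <- function(enriched_gene_ids = character(),
                          profile_group_of_feature = integer(),
                          discriminative_ids = character(),
                          fork_triplets = data.frame()) {
  structure(list(enriched_gene_ids = enriched_gene_ids,
                 profile_group_of_feature = profile_group_of_feature,
                 discriminative_ids = discriminative_ids,
                 fork_triplets = fork_triplets),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", length(x$enriched_gene_ids), "enriched genes,",
      length(x$discriminative_ids), "discriminative features,",
      nrow(x$fork_triplets), "forks\n")
  invisible(x)
}

#' Generate a synthetic joint gene + metabolite cohort
#'
#' Emits a joint [feature_matrix()] over `n_control_samples` control and
#' `n_treatment_samples` treatment samples, with the statistical structure
#' the downstream pipeline assumes:
#'
#' * every non-fork feature belongs to one of `n_profile_groups` latent
#'   profile groups and loads (with weight `profile_separation`) on a shared
#'   per-sample group factor, plus unit-sd feature noise, on the log scale;
#' * gene values are exponentiated and rounded to integers (heavy-tailed,
#'   count-like, log-transformable); metabolite values stay positive
#'   log-normal;
#' * `n_discriminative` randomly chosen features additionally receive a
#'   condition mean shift of `discriminative_shift` noise-sd units;
#' * each entry of `fork_specs` plants a metabolite triplet (A, B, C) with
#'   `A = slope * B/C + noise`, the slope switching between conditions;
#' * metabolite values in the bottom quartile of their compound are censored
#'   to missing with probability `missing_rate` (low-abundance censoring,
#'   matching minimum-value imputation downstream).
#'
#' Deterministic given `rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `cohort` (a [feature_matrix()]) and `truth`,
#'   a `planted_truth` record holding `enriched_gene_ids` (empty here),
#'   `profile_group_of_feature` (named integer; NA for fork metabolites),
#'   `discriminative_ids`, and `fork_triplets` (data.frame with A_id, B_id,
#'   C_id, slope_control, slope_treatment).
#' @export
generate_cohort <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(substream_seed(spec$rng_seed, "cohort"))
  n_samp <- spec$n_control_samples + spec$n_treatment_samples
  if (n_samp < 2L) stop("invalid synthetic_spec: need at least 2 samples")
  samp_ids <- c(sprintf("ctl%02d", seq_len(spec$n_control_samples)),
                sprintf("hs%02d", seq_len(spec$n_treatment_samples)))
  condition <- stats::setNames(
    c(rep("control", spec$n_control_samples),
      rep("treatment", spec$n_treatment_samples)), samp_ids)
  trt <- condition == "treatment"

  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  met_ids <- sprintf("m%04d", seq_len(spec$n_metabolites))
  n_forks <- length(spec$fork_specs)
  # fork triplets claim the last metabolite ids, three per fork
  fork_met <- if (n_forks > 0)
    met_ids[(spec$n_metabolites - 3L * n_forks + 1L):spec$n_metabolites]
  else character()
  plain_ids <- c(gene_ids, setdiff(met_ids, fork_met))
  feat_ids <- c(gene_ids, met_ids)
  kind <- stats::setNames(rep(c("gene", "metabolite"),
                              c(spec$n_genes, spec$n_metabolites)), feat_ids)

  # latent group factors: one unit-variance trajectory per group
  n_grp <- max(spec$n_profile_groups, 1L)
  grp_factor <- matrix(stats::rnorm(n_grp * n_samp), n_grp, n_samp)
  group <- stats::setNames(rep(NA_integer_, length(feat_ids)), feat_ids)
  if (length(plain_ids) && spec$n_profile_groups > 0)
    group[plain_ids] <- rep_len(seq_len(spec$n_profile_groups),
                                length(plain_ids))

  disc <- if (spec$n_discriminative > 0 && length(plain_ids))
    sort(sample(plain_ids, min(spec$n_discriminative, length(plain_ids))))
  else character()

  vals <- matrix(NA_real_, length(feat_ids), n_samp,
                 dimnames = list(feat_ids, samp_ids))
  mu_gene <- stats::runif(spec$n_genes, 3, 7)
  mu_met <- stats::runif(spec$n_metabolites, 0, 3)
  mu <- stats::setNames(c(mu_gene, mu_met), feat_ids)
  for (fid in plain_ids) {
    x <- mu[fid] + stats::rnorm(n_samp)
    marginal_sd <- 1
    if (!is.na(group[fid])) {
      x <- x + spec$profile_separation * grp_factor[group[fid], ]
      marginal_sd <- sqrt(1 + spec$profile_separation^2)
    }
    if (fid %in% disc)
      x <- x + spec$discriminative_shift * marginal_sd * as.numeric(trt)
    vals[fid, ] <- if (kind[fid] == "gene") pmax(1, round(exp(x))) else exp(x)
  }

  fork_tab <- data.frame(A_id = character(), B_id = character(),
                         C_id = character(), slope_control = numeric(),
                         slope_treatment = numeric())
  if (n_forks > 0) {
    for (i in seq_len(n_forks)) {
      fs <- spec$fork_specs[[i]]
      ids <- fork_met[(3L * i - 2L):(3L * i)]
      b <- exp(stats::rnorm(n_samp, 1.5, 0.35))
      cc <- exp(stats::rnorm(n_samp, 0.5, 0.35))
      slope <- ifelse(trt, fs[["slope_treatment"]], fs[["slope_control"]])
      a <- slope * b / cc
      if (fs[["noise_sd"]] > 0)
        a <- a + stats::rnorm(n_samp, 0, fs[["noise_sd"]])
      a[a <= 0] <- 1e-6   # keep the strict-positivity contract
      vals[ids[1L], ] <- a
      vals[ids[2L], ] <- b
      vals[ids[3L], ] <- cc
      fork_tab <- rbind(fork_tab, data.frame(
        A_id = ids[1L], B_id = ids[2L], C_id = ids[3L],
        slope_control = fs[["slope_control"]],
        slope_treatment = fs[["slope_treatment"]]))
    }
  }

  if (spec$missing_rate > 0 && spec$n_metabolites > 0) {
    for (fid in met_ids) {
      row <- vals[fid, ]
      low <- row <= stats::quantile(row, 0.25)
      drop <- low & stats::runif(n_samp) < spec$missing_rate
      if (sum(!drop) == 0L) drop[which.max(row)] <- FALSE
      vals[fid, drop] <- NA_real_
    }
  }

  truth <- planted_truth(profile_group_of_feature = group,
                         discriminative_ids = disc,
                         fork_triplets = fork_tab)
  list(cohort = feature_matrix(vals, kind, condition), truth = truth)
}

#' Serialize a planted-truth record to JSON
#'
#' @param truth a `planted_truth` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  obj <- list(
    enriched_gene_ids = truth$enriched_gene_ids,
    profile_group_of_feature = as.list(truth$profile_group_of_feature),
    discriminative_ids = truth$discriminative_ids,
    fork_triplets = truth$fork_triplets
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
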