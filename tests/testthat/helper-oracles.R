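# Independent oracles and tiny fixture builders shared across test files.

# Welch statistic straight from the defining formulas.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Independent OLS oracle for the interaction model: pivoted-QR fit through
# stats::lm/summary, a different algorithm from the package's closed-form
# normal-equations solve.
ols_fork_oracle <- function(a, r, d) {
  fit <- lm(a ~ r * d)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  list(slope_control = unname(cf["r"]),
       slope_treatment = unname(cf["r"] + cf["r:d"]),
       interaction_estimate = unname(cf["r:d"]),
       interaction_se = unname(sm["r:d", "Std. Error"]),
       interaction_p = unname(sm["r:d", "Pr(>|t|)"]))
}

# Minimal feature_matrix around a bare numeric matrix.
make_fm <- function(values, kind = NULL, n_control = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(kind))
    kind <- setNames(rep("metabolite", nrow(values)), rownames(values))
  if (is.null(n_control)) n_control <- ceiling(ncol(values) / 2)
  condition <- setNames(rep(c("control", "treatment"),
                            c(n_control, ncol(values) - n_control)),
                        colnames(values))
  feature_matrix(values, kind, condition)
}

# Cohort spec with no planted structure beyond what the caller asks for.
quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 0, n_metabolites = 0, n_enriched_genes = 0,
                   n_profile_groups = 0, n_discriminative = 0,
                   missing_rate = 0, rng_seed = 1)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}
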