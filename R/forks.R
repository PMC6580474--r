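#' Enumerate candidate metabolic-fork triplets
#'
#' A metabolic fork is a precursor routed to two competing fates; its
#' operational signature is a triplet (A, B, C) of metabolites in which the
#' regression slope of A on the ratio B/C differs between conditions.
#' Candidates for each role come from separate sets (e.g. sugars for A,
#' lipid intermediates for B, amino acids for C). Triplets are ordered:
#' (A, B, C) and (A, C, B) are distinct hypotheses, since cor(A, B/C) and
#' cor(A, C/B) differ.
#'
#' @param candidate_A,candidate_B,candidate_C character vectors of
#'   metabolite ids for each role.
#' @return a data.frame with columns `A_id`, `B_id`, `C_id`: all ordered
#'   triplets with three distinct members, deduplicated, sorted by
#'   (A, B, C) id.
#' @export
enumerate_triplets <- function(candidate_A, candidate_B, candidate_C) {
  if (!length(candidate_A) || !length(candidate_B) || !length(candidate_C))
    stop("every candidate role set must be non-empty")
  grid <- expand.grid(A_id = unique(candidate_A),
                      B_id = unique(candidate_B),
                      C_id = unique(candidate_C),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$A_id != grid$B_id & grid$A_id != grid$C_id &
                 grid$B_id != grid$C_id, , drop = FALSE]
  grid <- grid[order(grid$A_id, grid$B_id, grid$C_id), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Per-sample metabolite ratio B/C
#'
#' @param m a [feature_matrix()] with imputed (complete) metabolite values.
#' @param B_id,C_id metabolite feature ids.
#' @param epsilon denominators at or below this are considered degenerate.
#' @return numeric vector of per-sample ratios, or `NULL` (with attribute
#'   handling by the caller) if any denominator is degenerate; callers
#'   screening many triplets should use [fork_fit()], which flags rather
#'   than errors.
#' @export
ratio_series <- function(m, B_id, C_id, epsilon = 1e-12) {
  stopifnot(inherits(m, "feature_matrix"))
  b <- m$values[B_id, ]
  cc <- m$values[C_id, ]
  if (anyNA(b) || anyNA(cc))
    stop("ratio requires complete values for B and C; impute first")
  if (any(cc <= epsilon)) return(NULL)
  b / cc
}

#' Fit the metabolic-fork interaction model for one triplet
#'
#' Ordinary least squares of
#' `A ~ intercept + ratio + condition + ratio:condition` with the ratio
#' `B/C` and condition coded 0 = control, 1 = treatment. The interaction
#' coefficient is the difference between the treatment and control slopes;
#' its two-sided t-test p-value (n - 4 residual df) is the fork's
#' significance. Pearson correlations cor(A, B/C) are reported overall and
#' within each condition.
#'
#' Degenerate triplets are flagged rather than errored: `"degenerate-
#' denominator"` when any C is ~0, `"saturated"` when the fit is exact
#' (zero residual variance, so no error-based p exists), `"collinear"` when
#' the design is rank-deficient.
#'
#' @param m a [feature_matrix()] with complete metabolite values (ratios
#'   use post-imputation, pre-log abundances).
#' @param A_id,B_id,C_id metabolite ids of the triplet.
#' @param epsilon degenerate-denominator cutoff for C.
#' @return an object of class `fork_fit`: list with the triplet ids,
#'   `slope_control`, `slope_treatment`, `interaction_estimate`,
#'   `interaction_se`, `interaction_p`, `cor_overall`, `cor_control`,
#'   `cor_treatment`, `n_control`, `n_treatment`, `flag` (`""` if clean).
#' @export
fork_fit <- function(m, A_id, B_id, C_id, epsilon = 1e-12) {
  stopifnot(inherits(m, "feature_matrix"))
  ids <- c(A_id, B_id, C_id)
  if (length(unique(ids)) != 3L)
    stop("triplet members must be three distinct metabolites")
  unknown <- setdiff(ids, rownames(m$values))
  if (length(unknown)) stop("unknown metabolite id: ", unknown[1L])
  cond01 <- as.numeric(m$condition == "treatment")
  n_ctl <- sum(cond01 == 0)
  n_trt <- sum(cond01 == 1)
  base <- list(A_id = A_id, B_id = B_id, C_id = C_id,
               slope_control = NA_real_, slope_treatment = NA_real_,
               interaction_estimate = NA_real_, interaction_se = NA_real_,
               interaction_p = NA_real_, cor_overall = NA_real_,
               cor_control = NA_real_, cor_treatment = NA_real_,
               n_control = n_ctl, n_treatment = n_trt, flag = "")
  ratio <- ratio_series(m, B_id, C_id, epsilon = epsilon)
  if (is.null(ratio)) {
    base$flag <- "degenerate-denominator"
    return(structure(base, class = "fork_fit"))
  }
  a <- m$values[A_id, ]
  if (anyNA(a)) stop("A has missing values; impute first")
  if (n_ctl < 3L || n_trt < 3L)
    stop("need at least 3 samples per condition")
  res <- fork_ols(a, ratio, cond01)
  base[names(res)] <- res
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }
  base$cor_overall <- safe_cor(a, ratio)
  base$cor_control <- safe_cor(a[cond01 == 0], ratio[cond01 == 0])
  base$cor_treatment <- safe_cor(a[cond01 == 1], ratio[cond01 == 1])
  structure(base, class = "fork_fit")
}

# Closed-form OLS of a ~ 1 + r + d + r:d via the normal equations; kept
# lean because fork screens evaluate it for every enumerated triplet.
fork_ols <- function(a, ratio, cond01) {
  X <- cbind(1, ratio, cond01, ratio * cond01)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    return(list(flag = "collinear"))
  XtX_inv <- chol2inv(chol(XtX))
  beta <- drop(XtX_inv %*% crossprod(X, a))
  out <- list(slope_control = beta[2L],
              slope_treatment = beta[2L] + beta[4L],
              interaction_estimate = beta[4L])
  resid <- a - drop(X %*% beta)
  df <- length(a) - 4L
  s2 <- sum(resid^2) / df
  if (s2 <= 1e-20 * max(stats::var(a), 1)) {
    out$flag <- "saturated"   # exact fit: slopes valid, no error-based p
    return(out)
  }
  out$interaction_se <- sqrt(XtX_inv[4L, 4L] * s2)
  tval <- beta[4L] / out$interaction_se
  out$interaction_p <- 2 * stats::pt(-abs(tval), df)
  out$flag <- ""
  out
}

#' @export
print.fork_fit <- function(x, ...) {
  cat(sprintf("fork_fit: %s ~ %s/%s\n", x$A_id, x$B_id, x$C_id))
  cat(sprintf("  slopes: control %.4g, treatment %.4g (diff %.4g)\n",
              x$slope_control, x$slope_treatment, x$interaction_estimate))
  cat(sprintf("  interaction p: %s%s\n",
              format(x$interaction_p, digits = 4),
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Screen many triplets for metabolic forks
#'
#' Fits the interaction model to every triplet and ranks by the interaction
#' p-value. The significance call uses the raw p at `alpha` (the workflow's
#' historical decision rule); Benjamini-Hochberg adjusted p-values are
#' always reported alongside for multiplicity-aware reading.
#'
#' @param m a [feature_matrix()] with complete metabolite values.
#' @param triplets data.frame from [enumerate_triplets()].
#' @param alpha raw-p significance threshold (default 0.05).
#' @param adjust `"benjamini-hochberg"` (compute adjusted p; the default) or
#'   `"none"` (adjusted p reported as NA).
#' @return a data.frame sorted by ascending interaction p (ties by triplet
#'   id), columns `A_id`, `B_id`, `C_id`, `slope_control`,
#'   `slope_treatment`, `interaction_estimate`, `interaction_se`,
#'   `interaction_p`, `adjusted_p`, `cor_overall`, `cor_control`,
#'   `cor_treatment`, `significant`, `flag`.
#' @export
screen_forks <- function(m, triplets, alpha = 0.05,
                         adjust = c("benjamini-hochberg", "none")) {
  stopifnot(inherits(m, "feature_matrix"))
  adjust <- match.arg(adjust)
  n_t <- nrow(triplets)
  cond01 <- as.numeric(m$condition == "treatment")
  if (sum(cond01 == 0) < 3L || sum(cond01 == 1) < 3L)
    stop("need at least 3 samples per condition")
  vals <- m$values
  unknown <- setdiff(unique(unlist(triplets[, c("A_id", "B_id", "C_id")])),
                     rownames(vals))
  if (length(unknown)) stop("unknown metabolite id: ", unknown[1L])
  if (anyNA(vals[unique(unlist(triplets[, c("A_id", "B_id", "C_id")])), ]))
    stop("triplet members have missing values; impute first")
  cols <- c("slope_control", "slope_treatment", "interaction_estimate",
            "interaction_se", "interaction_p", "cor_overall",
            "cor_control", "cor_treatment")
  num <- matrix(NA_real_, n_t, length(cols), dimnames = list(NULL, cols))
  flag <- character(n_t)
  is_ctl <- cond01 == 0
  n_samp <- length(cond01)
  df_resid <- n_samp - 4L
  safe_cor_vec <- function(A, r) {
    # Pearson cor of each row of A with r, NA where either side is constant
    rs <- r - mean(r)
    Ac <- A - rowMeans(A)
    denom <- sqrt(rowSums(Ac^2) * sum(rs^2))
    out <- drop(Ac %*% rs) / denom
    out[denom <= 0] <- NA_real_
    out
  }
  # the design depends on (B, C) only; fit every A sharing a ratio at once
  key <- paste(triplets$B_id, triplets$C_id, sep = "\r")
  for (grp in split(seq_len(n_t), key)) {
    i1 <- grp[1L]
    b <- vals[triplets$B_id[i1], ]
    cc <- vals[triplets$C_id[i1], ]
    if (any(cc <= 1e-12)) {
      flag[grp] <- "degenerate-denominator"
      next
    }
    ratio <- b / cc
    X <- cbind(1, ratio, cond01, ratio * cond01)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) {
      flag[grp] <- "collinear"
      next
    }
    XtX_inv <- chol2inv(chol(XtX))
    A <- vals[triplets$A_id[grp], , drop = FALSE]
    beta <- XtX_inv %*% crossprod(X, t(A))        # 4 x |grp|
    resid <- t(A) - X %*% beta
    s2 <- colSums(resid^2) / df_resid
    saturated <- s2 <= 1e-20 * pmax(apply(A, 1L, stats::var), 1)
    se <- sqrt(XtX_inv[4L, 4L] * s2)
    num[grp, "slope_control"] <- beta[2L, ]
    num[grp, "slope_treatment"] <- beta[2L, ] + beta[4L, ]
    num[grp, "interaction_estimate"] <- beta[4L, ]
    num[grp, "interaction_se"] <- ifelse(saturated, NA_real_, se)
    num[grp, "interaction_p"] <- ifelse(saturated, NA_real_,
      2 * stats::pt(-abs(beta[4L, ] / se), df_resid))
    flag[grp] <- ifelse(saturated, "saturated", "")
    num[grp, "cor_overall"] <- safe_cor_vec(A, ratio)
    num[grp, "cor_control"] <-
      safe_cor_vec(A[, is_ctl, drop = FALSE], ratio[is_ctl])
    num[grp, "cor_treatment"] <-
      safe_cor_vec(A[, !is_ctl, drop = FALSE], ratio[!is_ctl])
  }
  out <- data.frame(triplets[, c("A_id", "B_id", "C_id")], num,
                    flag = flag, stringsAsFactors = FALSE)
  out$adjusted_p <- if (adjust == "benjamini-hochberg")
    stats::p.adjust(out$interaction_p, method = "BH") else NA_real_
  out$significant <- !is.na(out$interaction_p) & out$interaction_p < alpha
  out <- out[order(out$interaction_p, out$A_id, out$B_id, out$C_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("A_id", "B_id", "C_id", "slope_control", "slope_treatment",
          "interaction_estimate", "interaction_se", "interaction_p",
          "adjusted_p", "cor_overall", "cor_control", "cor_treatment",
          "significant", "flag")]
}
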