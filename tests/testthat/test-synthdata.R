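test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_genes = -1), "n_genes")
  expect_error(synthetic_spec(n_genes = 5, n_enriched_genes = 6),
               "n_enriched_genes")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(
    synthetic_spec(n_genes = 0, n_enriched_genes = 0, n_metabolites = 2,
                   n_discriminative = 0,
                   fork_specs = list(list(slope_control = 1,
                                          slope_treatment = 1,
                                          noise_sd = 0))),
    "fork_specs")
})

test_that("generator is deterministic and substreams are independent", {
  spec <- synthetic_spec(n_genes = 30, n_metabolites = 10,
                         n_enriched_genes = 5, rng_seed = 11)
  g1 <- generate_compendium(spec)
  g2 <- generate_compendium(spec)
  expect_identical(g1$compendium$values, g2$compendium$values)
  expect_identical(g1$truth$enriched_gene_ids, g2$truth$enriched_gene_ids)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$cohort$values, c2$cohort$values)
  # cohort and compendium draw from distinct named substreams: regenerating
  # one between calls does not perturb the other
  g3 <- generate_compendium(spec)
  expect_identical(g1$compendium$values, g3$compendium$values)
})

test_that("nothing is planted when nothing is requested", {
  spec <- synthetic_spec(n_genes = 40, n_metabolites = 8,
                         n_enriched_genes = 0, n_discriminative = 0,
                         missing_rate = 0, rng_seed = 3)
  g <- generate_compendium(spec)
  expect_length(g$truth$enriched_gene_ids, 0)
  co <- generate_cohort(spec)
  expect_false(anyNA(co$cohort$values))
  expect_length(co$truth$discriminative_ids, 0)
})

test_that("metabolite values are strictly positive before missingness", {
  for (seed in 1:5) {
    spec <- synthetic_spec(n_genes = 5, n_metabolites = 40,
                           n_enriched_genes = 0, missing_rate = 0,
                           fork_specs = list(list(slope_control = 2,
                                                  slope_treatment = 5,
                                                  noise_sd = 0.5)),
                           rng_seed = seed)
    co <- generate_cohort(spec)
    met <- co$cohort$values[co$cohort$kind == "metabolite", ]
    expect_true(all(met > 0))
  }
})

test_that("missingness censors only low-abundance metabolite values", {
  spec <- synthetic_spec(n_genes = 10, n_metabolites = 50,
                         n_enriched_genes = 0, missing_rate = 0.8,
                         rng_seed = 5)
  co <- generate_cohort(spec)
  vals <- co$cohort$values
  expect_false(anyNA(vals[co$cohort$kind == "gene", ]))
  met <- vals[co$cohort$kind == "metabolite", , drop = FALSE]
  expect_gt(sum(is.na(met)), 0)
  for (i in seq_len(nrow(met))) {
    row <- met[i, ]
    if (anyNA(row)) {
      # only entries in the compound's bottom quartile are censorable, so
      # at most ~a quarter of the row (interpolated quantile can admit one
      # extra tied value) can go missing even at high missing_rate
      expect_lte(sum(is.na(row)), ceiling(0.25 * length(row)) + 1L)
    }
  }
})

test_that("profile groups induce stronger within- than between-group correlation", {
  spec <- synthetic_spec(n_genes = 0, n_metabolites = 60,
                         n_enriched_genes = 0, n_profile_groups = 3,
                         profile_separation = 2, n_discriminative = 0,
                         missing_rate = 0, rng_seed = 9)
  co <- generate_cohort(spec)
  grp <- co$truth$profile_group_of_feature[rownames(co$cohort$values)]
  cm <- cor(t(log(co$cohort$values)))
  same <- outer(grp, grp, "==") & upper.tri(cm)
  diff <- outer(grp, grp, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))
})

test_that("planted discriminative features are recovered by Welch across seeds", {
  hits <- 0L
  n_seeds <- 100L
  for (seed in seq_len(n_seeds)) {
    spec <- synthetic_spec(n_genes = 6, n_metabolites = 6,
                           n_enriched_genes = 0, n_profile_groups = 3,
                           profile_separation = 4, n_discriminative = 4,
                           discriminative_shift = 3,
                           n_control_samples = 8, n_treatment_samples = 8,
                           missing_rate = 0, rng_seed = seed)
    co <- generate_cohort(spec)
    std <- log_transform(co$cohort)
    w <- welch_test(subset_features(std, co$truth$discriminative_ids))
    if (all(w$p < 0.01)) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * n_seeds)
})

test_that("noiseless planted fork slopes are recovered exactly by OLS", {
  spec <- synthetic_spec(n_genes = 0, n_metabolites = 6,
                         n_enriched_genes = 0, n_discriminative = 0,
                         missing_rate = 0,
                         fork_specs = list(
                           list(slope_control = 2, slope_treatment = 5,
                                noise_sd = 0),
                           list(slope_control = 2, slope_treatment = 2,
                                noise_sd = 0)),
                         rng_seed = 21)
  co <- generate_cohort(spec)
  tr <- co$truth$fork_triplets
  f1 <- fork_fit(co$cohort, tr$A_id[1], tr$B_id[1], tr$C_id[1])
  expect_equal(f1$slope_control, 2, tolerance = 1e-8)
  expect_equal(f1$slope_treatment, 5, tolerance = 1e-8)
  expect_equal(f1$interaction_estimate, 3, tolerance = 1e-8)
  f2 <- fork_fit(co$cohort, tr$A_id[2], tr$B_id[2], tr$C_id[2])
  expect_lt(abs(f2$interaction_estimate), 1e-8)
  expect_identical(f2$flag, "saturated")
})

test_that("planted truth round-trips through JSON", {
  spec <- synthetic_spec(n_genes = 10, n_metabolites = 8,
                         n_enriched_genes = 0, n_discriminative = 3,
                         missing_rate = 0, rng_seed = 2)
  co <- generate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_planted_truth(co$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$discriminative_ids, co$truth$discriminative_ids)
})
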