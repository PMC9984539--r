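test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_case = 0), "n_case")
  expect_error(cohort_config(n_metabolites = -3), "n_metabolites")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(outlier_rate = 1.2), "outlier_rate")
  expect_error(cohort_config(n_metabolites = 3,
                             n_informative_per_layer = c(metabolite = 5,
                                                         protein = 1,
                                                         mirna = 1)),
               "n_informative_per_layer")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
})

test_that("the same config and seed give a byte-identical cohort", {
  cc <- cohort_config(n_case = 8, n_control = 8, n_metabolites = 20, seed = 11)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and a different seed gives a different cohort
  cc2 <- cohort_config(n_case = 8, n_control = 8, n_metabolites = 20, seed = 12)
  expect_false(identical(generate_cohort(cc2)$metabolites, a$metabolites))
})

test_that("tables share ordered sample ids and truth features exist", {
  coh <- generate_cohort(cohort_config(n_case = 10, n_control = 12, seed = 4))
  ids <- coh$metadata$sample_id
  expect_identical(rownames(coh$metabolites), ids)
  expect_identical(rownames(coh$proteins), ids)
  expect_identical(rownames(coh$mirna_cq), ids)
  expect_true(all(coh$truth$metabolites$feature_id %in%
                    colnames(coh$metabolites)))
  expect_true(all(coh$truth$proteins$feature_id %in% colnames(coh$proteins)))
  expect_true(all(coh$truth$mirnas$feature_id %in% colnames(coh$mirna_cq)))
  expect_equal(sum(coh$metadata$group == "case"), 10)
})

test_that("effect_size = 0 leaves every feature exchangeable between groups", {
  coh <- generate_cohort(cohort_config(n_case = 40, n_control = 40,
                                       n_metabolites = 100, effect_size = 0,
                                       seed = 21))
  x <- log(as_matrix_plain(coh$metabolites))
  case <- coh$metadata$group == "case"
  # per-feature standardized mean difference should hover near 0:
  # check the pooled distribution of |diff| / SE over features
  z <- apply(x, 2, function(v) {
    se <- sqrt(var(v[case]) / sum(case) + var(v[!case]) / sum(!case))
    (mean(v[case]) - mean(v[!case])) / se
  })
  expect_lt(mean(abs(z) > 4), 0.01)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("a d = 3 informative feature separates groups in nearly all seeds", {
  hits <- 0L
  n_seeds <- 200L
  for (s in seq_len(n_seeds)) {
    coh <- generate_cohort(cohort_config(n_case = 40, n_control = 40,
                                         n_metabolites = 3, n_proteins = 1,
                                         n_mirnas = 1,
                                         n_informative_per_layer =
                                           c(metabolite = 1, protein = 0,
                                             mirna = 0),
                                         effect_size = 3, seed = s))
    x <- log(as_matrix_plain(coh$metabolites))
    case <- coh$metadata$group == "case"
    tt <- t.test(x[case, 1], x[!case, 1])
    # null 0.999 quantile of the Welch statistic
    if (abs(tt$statistic) > qt(0.999, tt$parameter)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("zero rates leave the cohort untouched; positive rates are logged", {
  cc <- cohort_config(n_case = 10, n_control = 10, n_metabolites = 25,
                      missing_rate = 0, outlier_rate = 0, seed = 5)
  coh <- generate_cohort(cc)
  expect_identical(inject_missingness_and_outliers(coh, cc), coh)

  cc2 <- cohort_config(n_case = 25, n_control = 25, n_metabolites = 100,
                       missing_rate = 0.1, outlier_rate = 0, seed = 5)
  coh2 <- inject_missingness_and_outliers(generate_cohort(cc2), cc2)
  n_missing <- sum(is.na(as_matrix_plain(coh2$metabolites)))
  n_cells <- 50 * 100
  # central 99% binomial interval for Binomial(5000, 0.1)
  expect_gte(n_missing, qbinom(0.005, n_cells, 0.1))
  expect_lte(n_missing, qbinom(0.995, n_cells, 0.1))
  expect_equal(sum(coh2$truth$missing$layer == "metabolite"), n_missing)
})

test_that("every injected outlier is caught by the 2-SD exclusion rule", {
  cc <- cohort_config(n_case = 15, n_control = 15, n_metabolites = 40,
                      missing_rate = 0, outlier_rate = 0.02, seed = 9)
  coh <- inject_missingness_and_outliers(generate_cohort(cc), cc)
  out <- coh$truth$outliers
  expect_gt(nrow(out), 0)
  met <- out[out$layer == "metabolite", ]
  res <- exclude_outliers(coh$metabolites, coh$metadata, "group", k_sd = 2)
  flagged <- paste(res$qc$excluded_cells$sample_id,
                   res$qc$excluded_cells$feature_id)
  expect_true(all(paste(met$sample_id, met$feature_id) %in% flagged))
})

test_that("cohort CSV round trip preserves the tables", {
  coh <- generate_cohort(cohort_config(n_case = 5, n_control = 5,
                                       n_metabolites = 8, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metabolites.csv", "proteins.csv", "mirna_cq.csv", "metadata.csv",
      "truth.json")))))
  back <- read_feature_table(file.path(dir, "metabolites.csv"), "metabolite")
  expect_equal(as_matrix_plain(back), as_matrix_plain(coh$metabolites),
               tolerance = 1e-12)
})
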