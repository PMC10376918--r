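test_that("simulate_cohort is deterministic and passes core validation", {
  cfg <- simulation_config(n_features_per_class = 8, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_silent(validate_expression_matrix(a$expr))
  expect_true(validate_annotations(a$expr, a$samples, a$features))
  # 2 fractions x 5 ages x 4 replicates
  expect_equal(ncol(a$expr$values), 2 * 5 * 4)
  expect_equal(nrow(a$expr$values), 8 * 10)
  # sample truth follows the young/middle/old grouping
  expect_equal(a$truth$samples$age_group,
               age_group_of(a$samples$age_months))
})

test_that("null cohort (effect_size 0) has age correlations centred at 0", {
  cfg <- simulation_config(n_features_per_class = 30, effect_size = 0,
                           seed = 5)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$features$planted_shape == "flat"))
  st <- trajectory_stats(filter_expressed(normalize_rpm(sim$expr)),
                         sim$samples)
  r <- st$pearson_r[is.finite(st$pearson_r)]
  # mean r near 0 and mean |r| consistent with the null at n = 20
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(mean(abs(r)), 0.30)
})

test_that("planted linear signs are recovered at effect_size 2", {
  cfg <- simulation_config(linear_fraction = 0.5, nonlinear_fraction = 0,
                           effect_size = 2, seed = 29)
  sim <- simulate_cohort(cfg)
  st <- trajectory_stats(filter_expressed(normalize_rpm(sim$expr)),
                         sim$samples)
  tr <- sim$truth$features
  for (fr in c("EV", "fc")) {
    s <- st[st$fraction == fr, ]
    sgn <- (if (fr == "EV") tr$sign_EV else tr$sign_fc)[
      match(s$feature_id, tr$feature_id)]
    lin <- sgn != 0 & is.finite(s$pearson_r)
    expect_gt(mean(sign(s$pearson_r[lin]) == sgn[lin]), 0.9)
  }
})

test_that("discordant features flip sign between fractions", {
  cfg <- simulation_config(linear_fraction = 0.5, discordant_fraction = 0.4,
                           seed = 7)
  tr <- simulate_cohort(cfg)$truth$features
  lin <- tr$sign_fc != 0
  expect_equal(sum(tr$sign_EV[lin] != tr$sign_fc[lin]),
               round(0.4 * sum(lin)))
  expect_true(all(tr$sign_EV[!lin] == 0))
})

test_that("degenerate configs are rejected", {
  expect_error(simulation_config(n_features_per_class = 0))
  expect_error(simulation_config(replicates_per_group_per_fraction = 0))
  expect_error(simulation_config(linear_fraction = 0.7,
                                 nonlinear_fraction = 0.5))
  expect_error(simulation_config(dispersion = 0))
})

test_that("simulate_target_atlas plants recoverable repression", {
  atlas <- simulate_target_atlas(n_mirnas = 6, n_genes = 40,
                                 repression_strength = 1, noise_sd = 0.05,
                                 seed = 2)
  # determinism
  atlas2 <- simulate_target_atlas(n_mirnas = 6, n_genes = 40,
                                  repression_strength = 1, noise_sd = 0.05,
                                  seed = 2)
  expect_identical(atlas$edges, atlas2$edges)
  expect_identical(atlas$tissues, atlas2$tissues)
  # single planted repressor chain: up-miRNA's strong target goes down
  one <- simulate_target_atlas(n_mirnas = 1, n_genes = 1, n_tissues = 1,
                               repression_strength = 1, noise_sd = 0.01,
                               seed = 3, prop_strong = 1)
  g <- one$tissues[[1]][1, ]
  expect_lt(cor(g, one$ages), 0)
  # null: zero repression leaves gene trends independent of regulator signs
  null <- simulate_target_atlas(n_mirnas = 6, n_genes = 60,
                                repression_strength = 0, noise_sd = 0.05,
                                seed = 4)
  expect_true(all(null$truth$gene_slope == 0))
  expect_error(simulate_target_atlas(n_mirnas = 10, n_genes = 5), "n_genes")
})

test_that("simulate_qpcr plants exact noiseless fold changes", {
  ct <- simulate_qpcr(n_young = 3, n_old = 3,
                      true_log2fc = c(assayX = 1.5), noise_sd = 0, seed = 1)
  res <- delta_delta_ct(ct, "assayX")
  expect_equal(res$log2fc, 1.5)
  ct0 <- simulate_qpcr(true_log2fc = c(assayX = 0), noise_sd = 0, seed = 1)
  expect_equal(delta_delta_ct(ct0, "assayX")$log2fc, 0)
  expect_error(simulate_qpcr(noise_sd = -1), "noise_sd")
})

test_that("Monte-Carlo qPCR recovery is unbiased under noise", {
  # scaled down from 1000 replicates for test-suite runtime: 200 seeds
  est <- vapply(1:200, function(s) {
    ct <- simulate_qpcr(n_young = 4, n_old = 4,
                        true_log2fc = c(a = 1.2), noise_sd = 0.2, seed = s)
    delta_delta_ct(ct, "a")$log2fc
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.2), 0.05)
})
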