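ages5 <- c(2, 6, 8, 12, 18)

test_that("age_correlation matches the direct-formula oracle", {
  expect_equal(age_correlation(ages5, ages5), 1)
  expect_equal(age_correlation(-ages5, ages5), -1)
  # frozen value from the textbook covariance / sd*sd formula
  expect_equal(age_correlation(c(0, 1, 0, 1, 0), ages5),
               -0.029934217004, tolerance = 1e-10)
  expect_true(is.na(age_correlation(rep(3, 5), ages5)))
  expect_error(age_correlation(1:4, ages5), "length")
  expect_error(age_correlation(1:5, rep(2, 5)), "equal")
})

test_that("distance_correlation: trivial cases and conventions", {
  expect_equal(distance_correlation(1:3, 1:3), 1)
  expect_equal(distance_correlation(1:5, rep(2, 5)), 0)
  expect_error(distance_correlation(1:3, 1:4), "length")
})

test_that("distance_correlation equals brute-force double centring", {
  # frozen oracle value for x = 1:4, y = x^2
  expect_equal(distance_correlation(1:4, (1:4)^2),
               0.988057560083, tolerance = 1e-10)
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20) + 0.3 * x^2
    expect_equal(distance_correlation(x, y), bf_dcor(x, y),
                 tolerance = 1e-10)
  }
})

test_that("distance_correlation is translation and scale invariant", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    d <- distance_correlation(x, y)
    expect_equal(distance_correlation(3 * x + 7, y), d, tolerance = 1e-12)
    expect_equal(distance_correlation(x, 0.2 * y - 5), d, tolerance = 1e-12)
  }
})

test_that("classify_nonlinear applies the residual rule and sign convention", {
  # features on a known smooth curve -> near-zero residuals, none flagged;
  # two planted outliers deviate by 0.2
  set.seed(6)
  r <- seq(-0.9, 0.9, length.out = 60)
  d <- 0.3 + 0.5 * abs(r)
  stats <- data.frame(feature_id = sprintf("f%02d", 1:60), fraction = "EV",
                      pearson_r = r, dcor = d)
  out <- classify_nonlinear(stats)
  expect_true(all(out$category == "linear"))
  expect_true(all(abs(out$residual) < 0.05))
  stats$dcor[10] <- stats$dcor[10] + 0.20   # at r < 0
  stats$dcor[50] <- stats$dcor[50] + 0.20   # at r > 0
  out2 <- classify_nonlinear(stats)
  expect_equal(out2$category[10], "nonlinear_negative")
  expect_equal(out2$category[50], "nonlinear_positive")
  expect_lt(sum(out2$category != "linear"), 6)  # spline stays on the bulk
  expect_error(classify_nonlinear(stats[1:5, ]), "df")
})

test_that("flagged set shrinks as the threshold grows", {
  sim <- simulate_cohort(simulation_config(seed = 13))
  st <- trajectory_stats(filter_expressed(normalize_rpm(sim$expr)),
                         sim$samples)
  s <- st[st$fraction == "EV", ]
  n_flagged <- vapply(c(0.05, 0.1, 0.15, 0.25), function(th) {
    out <- classify_nonlinear(s, threshold = th)
    sum(out$category != "linear", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("quadrant_concordance counts, exclusions and chi-square", {
  q <- quadrant_concordance(c(0.5, -0.5), c(0.5, 0.5))
  expect_equal(unname(q$fractions),c(0.5, 0, 0.5, 0))
  expect_equal(sum(q$fractions), 1, tolerance = 1e-9)
  # zero correlations excluded and counted
  q2 <- quadrant_concordance(c(0.5, 0, -0.2, NA), c(0.5, 1, -1, 0.3))
  expect_equal(q2$n_excluded, 2)
  expect_equal(sum(q2$counts) + q2$n_excluded, 4)
  # chi-square path matches the textbook oracle (expected counts >= 5)
  r_ev <- c(rep(1, 40), rep(-1, 60))
  r_fc <- c(rep(1, 30), rep(-1, 10), rep(1, 30), rep(-1, 30))
  q3 <- quadrant_concordance(r_ev, r_fc)
  expect_equal(unname(q3$counts), c(30, 10, 30, 30))
  oracle <- bf_chisq_gof(c(30, 10, 30, 30))
  expect_equal(q3$chisq_stat, oracle$stat)
  expect_equal(q3$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(q3$chisq_stat, 12)
  # exact multinomial fallback at small n agrees with chisq.test simulation
  q4 <- quadrant_concordance(c(1, 1, 1, -1, -1, 1), c(1, 1, -1, 1, -1, -1))
  expect_equal(q4$method, "exact multinomial")
  expect_true(q4$p_value > 0 && q4$p_value <= 1)
  expect_error(quadrant_concordance(c(0, 0), c(1, 1)), "no features")
})

test_that("mean_shift_permutation_test: determinism and trivial null", {
  sim <- simulate_cohort(simulation_config(n_features_per_class = 5, seed = 9))
  rpm <- filter_expressed(normalize_rpm(sim$expr))
  frac <- sim$samples$fraction[match(rpm$sample_ids, sim$samples$sample_id)]
  ages <- sim$samples$age_months[match(rpm$sample_ids, sim$samples$sample_id)]
  ev <- rpm[, frac == "EV"]; fc <- rpm[, frac == "fc"]
  r1 <- mean_shift_permutation_test(ev, fc, ages[frac == "EV"],
                                    ages[frac == "fc"],
                                    n_permutations = 50, seed = 4)
  r2 <- mean_shift_permutation_test(ev, fc, ages[frac == "EV"],
                                    ages[frac == "fc"],
                                    n_permutations = 50, seed = 4)
  expect_identical(r1$null_means, r2$null_means)
  expect_gte(r1$p_value, 1 / 51)
  # identical matrices give observed difference exactly 0
  r0 <- mean_shift_permutation_test(ev, ev, ages[frac == "EV"],
                                    ages[frac == "EV"],
                                    n_permutations = 20, seed = 1)
  expect_equal(r0$observed_difference, 0)
  expect_error(mean_shift_permutation_test(ev, fc, ages[frac == "EV"],
                                           ages[frac == "fc"],
                                           n_permutations = 0), "permutations")
})

test_that("baseline_relative_expression anchors at 0 and tracks planting", {
  sim <- simulate_cohort(simulation_config(n_features_per_class = 20,
                                           seed = 21))
  rpm <- normalize_rpm(sim$expr)
  rel <- baseline_relative_expression(rpm, sim$samples, sim$features)
  base <- rel[rel$age_months == 2, ]
  expect_true(all(abs(base$log2_ratio) < 1e-12, na.rm = TRUE))
  # constant expression -> all zero
  v <- matrix(50, 4, 10,
              dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:10)))
  x <- expression_matrix(v, "rpm")
  samples <- data.frame(sample_id = sprintf("s%d", 1:10), mouse_id = "m",
                        age_months = rep(ages5, 2),
                        fraction = rep(c("EV", "fc"), each = 5))
  feats <- data.frame(feature_id = sprintf("f%d", 1:4), rna_class = "miRNA")
  rel0 <- baseline_relative_expression(x, samples, feats)
  expect_true(all(rel0$log2_ratio == 0))
  # doubling at 18 months vs baseline -> +1
  v2 <- v; v2[, samples$age_months == 18] <- 100
  rel2 <- baseline_relative_expression(expression_matrix(v2, "rpm"),
                                       samples, feats)
  expect_true(all(rel2$log2_ratio[rel2$age_months == 18] == 1))
})
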