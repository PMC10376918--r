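test_that("read_expression parses and cross-validates a well-formed triple", {
  dir <- toy_cohort_files()
  dat <- read_expression(file.path(dir, "counts.tsv"),
                         file.path(dir, "samples.tsv"),
                         file.path(dir, "features.tsv"))
  expect_s3_class(dat$expr, "ExpressionMatrix")
  expect_equal(dim(dat$expr), c(3L, 2L))
  expect_equal(dat$expr$feature_ids, c("fA", "fB", "fC"))
  expect_equal(dat$expr$values["fB", "s1"], 8)
})

test_that("read_expression rejects duplicate and unannotated ids", {
  dir <- toy_cohort_files()
  # duplicated feature row
  m <- read.delim(file.path(dir, "counts.tsv"))
  write.table(rbind(m, m[1, ]), file.path(dir, "dup.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(dir, "dup.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "features.tsv")),
               "duplicate feature")
  # sample sheet missing a matrix column: error names the sample
  ss <- read.delim(file.path(dir, "samples.tsv"))
  write.table(ss[1, ], file.path(dir, "samples1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(dir, "counts.tsv"),
                               file.path(dir, "samples1.tsv"),
                               file.path(dir, "features.tsv")),
               "s2")
  # negative entry
  m2 <- m; m2$s1[1] <- -1
  write.table(m2, file.path(dir, "neg.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(dir, "neg.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "features.tsv")),
               "non-negative")
})

test_that("normalize_rpm scales columns to one million and keeps order", {
  x <- toy_matrix(cbind(c(2, 8), c(5, 0)))
  r <- normalize_rpm(x)
  expect_equal(r$unit, "rpm")
  expect_equal(unname(r$values[, 1]), c(2e5, 8e5))
  expect_equal(unname(r$values[, 2]), c(1e6, 0))
  expect_equal(colSums(r$values), c(s1 = 1e6, s2 = 1e6))
  # rank order within sample preserved
  set.seed(42)
  y <- toy_matrix(matrix(rpois(60, 20) + 1, 10, 6))
  ry <- normalize_rpm(y)
  for (j in 1:6) expect_equal(order(ry$values[, j]), order(y$values[, j]))
})

test_that("normalize_rpm names the sample with a zero library", {
  x <- toy_matrix(cbind(c(1, 2), c(0, 0)))
  expect_error(normalize_rpm(x), "zero library size.*s2")
  expect_error(normalize_rpm(normalize_rpm(toy_matrix(cbind(c(1, 2))))),
               "raw counts")
})

test_that("filter_expressed applies an inclusive threshold and is idempotent", {
  # feature maxima exactly 5.0 (retained, inclusive rule) and 4.99 (dropped)
  v2 <- rbind(a = c(5, 1), b = c(4.99, 1), c = c(7, 7))
  y <- toy_matrix(v2, unit = "rpm",
                  features = c("a", "b", "c"), samples = c("s1", "s2"))
  f <- filter_expressed(y)
  expect_setequal(f$feature_ids, c("a", "c"))
  expect_equal(f$sample_ids, y$sample_ids)
  # identity at min_rpm = 0, idempotence at default
  expect_equal(filter_expressed(y, min_rpm = 0)$feature_ids, y$feature_ids)
  expect_equal(filter_expressed(f)$values, f$values)
  expect_error(filter_expressed(toy_matrix(cbind(c(1, 2)))), "RPM")
})

test_that("class_summary: read shares, detection curves, overlap sets", {
  sim <- simulate_cohort(simulation_config(n_features_per_class = 10, seed = 3))
  rpm <- normalize_rpm(sim$expr)
  cs <- class_summary(rpm, sim$features, sim$samples)
  # read shares per fraction sum to 1
  for (fr in unique(cs$read_share$fraction)) {
    expect_equal(sum(cs$read_share$share[cs$read_share$fraction == fr]), 1,
                 tolerance = 1e-9)
  }
  # detection curves monotone non-increasing in threshold
  det <- cs$detection
  for (key in unique(paste(det$rna_class, det$fraction))) {
    sub <- det[paste(det$rna_class, det$fraction) == key, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$detected_fraction) <= 1e-12))
  }
  # threshold 0 detects every class with any feature
  expect_true(all(det$detected_fraction[det$threshold == 0] == 1))
  expect_true(all(rowSums(cs$overlap[, c("ev_only", "fc_only", "both")]) == 10))
})

test_that("class_summary counts fraction-specific detections", {
  v <- rbind(evonly = c(100, 0), both = c(50, 50))
  x <- toy_matrix(v * 100, unit = "raw_counts")
  rpm <- normalize_rpm(x)
  feats <- data.frame(feature_id = c("f1", "f2"), rna_class = "miRNA")
  samples <- data.frame(sample_id = c("s1", "s2"), mouse_id = "m1",
                        age_months = c(2, 2), fraction = c("EV", "fc"))
  cs <- class_summary(rpm, feats, samples)
  expect_equal(cs$overlap$ev_only, 1)
  expect_equal(cs$overlap$both, 1)
  expect_equal(cs$overlap$fc_only, 0)
})
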