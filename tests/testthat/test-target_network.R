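mk_edges <- function(...) {
  df <- data.frame(...)
  names(df) <- c("mirna_id", "gene_id", "evidence")
  df
}

test_that("build_network filters evidence and finds hubs", {
  edges <- mk_edges(
    c("m1", "m2", "m3", "m4", "m4", "m4", "m4", "m4"),
    c("g1", "g1", "g1", "g2", "g2", "g2", "g2", "g2"),
    c("strong", "strong", "strong", "strong", "weak", "weak",
      "weak", "weak"))
  corr <- c(m1 = 0.8, m2 = 0.7, m3 = -0.6, m4 = 0.5)
  net <- build_network(edges, corr)
  # g1: 3 strong regulators -> hub; g2: 1 strong (duplicates collapse)
  expect_equal(net$hub_genes, "g1")
  expect_equal(unname(net$in_degree["g2"]), 1L)
  # weak edges never increase degree under the strong filter
  net_all <- build_network(edges, corr, evidence_filter = c("strong", "weak"))
  expect_true(all(net$in_degree <= net_all$in_degree[names(net$in_degree)]))
  # hub set shrinks as the threshold rises
  expect_length(build_network(edges, corr, hub_threshold = 4)$hub_genes, 0)
  # empty result is a warning, not an error
  expect_warning(empty <- build_network(edges[0, ], corr), "empty")
  expect_equal(nrow(empty$edges), 0)
  # miRNAs without correlation annotation are dropped with a warning
  expect_warning(net2 <- build_network(edges, corr[c("m1", "m2")]), "m3")
  expect_false("m3" %in% net2$mirnas)
})

test_that("planted repression yields signed target concordance", {
  atlas <- simulate_target_atlas(n_mirnas = 8, n_genes = 50, n_tissues = 3,
                                 repression_strength = 1, noise_sd = 0.05,
                                 seed = 6)
  mcorr <- atlas$truth$mirna_slope   # sign of planted slope
  net <- build_network(atlas$edges, mcorr)
  groups <- list(up = names(mcorr)[mcorr > 0], down = names(mcorr)[mcorr < 0])
  conc <- target_age_concordance(net, atlas$tissues, groups)
  up <- conc[conc$group == "up", ]
  dn <- conc[conc$group == "down", ]
  expect_true(all(up$mean_target_corr < 0))
  expect_true(all(dn$mean_target_corr > 0))
  # symmetry: negating all planted slopes flips every concordance sign
  neg <- lapply(atlas$tissues, function(m) {
    flipped <- -(m - rowMeans(m)) + rowMeans(m)
    dimnames(flipped) <- dimnames(m); flipped
  })
  conc_neg <- target_age_concordance(net, neg, groups)
  expect_equal(conc_neg$mean_target_corr, -conc$mean_target_corr,
               tolerance = 1e-10)
  # group with no targets is undefined with n = 0
  conc0 <- target_age_concordance(net, atlas$tissues, list(none = "miR-99"))
  expect_true(all(is.na(conc0$mean_target_corr)))
  expect_true(all(conc0$n_targets == 0))
})

test_that("zero repression gives near-zero mean concordance", {
  means <- vapply(1:5, function(s) {
    atlas <- simulate_target_atlas(n_mirnas = 6, n_genes = 60,
                                   repression_strength = 0, noise_sd = 0.2,
                                   seed = s)
    mcorr <- atlas$truth$mirna_slope
    net <- build_network(atlas$edges, mcorr)
    conc <- target_age_concordance(net, atlas$tissues,
                                   list(up = names(mcorr)[mcorr > 0]))
    mean(conc$mean_target_corr, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.2)
})

test_that("direct_target_correlation orders miRNAs by mean and finds -1", {
  samples <- sprintf("s%d", 1:6)
  mirna <- rbind(mA = 1:6, mB = c(2, 1, 4, 3, 6, 5))
  colnames(mirna) <- samples
  genes <- rbind(g1 = -(1:6), g2 = 1:6, g3 = c(6, 5, 4, 3, 2, 1) * 2)
  colnames(genes) <- samples
  edges <- mk_edges(c("mA", "mA", "mB"), c("g1", "g2", "g3"),
                    rep("strong", 3))
  net <- build_network(edges, c(mA = 0.9, mB = 0.5))
  res <- direct_target_correlation(mirna, genes, net)
  expect_equal(res$mA$correlation[res$mA$gene_id == "g1"], -1)
  # mA mean = mean(-1, 1) = 0; mB: cor with a decreasing gene < 0 -> first
  expect_equal(names(res)[1], "mB")
  expect_true(!is.unsorted(attr(res, "mean_corr")))
  expect_error(direct_target_correlation(mirna[, 1:2], genes[, 1:2], net),
               "shared samples")
})

test_that("planted repressors occupy the most negative end", {
  atlas <- simulate_target_atlas(n_mirnas = 6, n_genes = 40, n_tissues = 1,
                                 repression_strength = 2, noise_sd = 0.05,
                                 seed = 14, prop_strong = 1)
  net <- build_network(atlas$edges, atlas$truth$mirna_slope)
  res <- direct_target_correlation(atlas$mirna_expr, atlas$tissues[[1]], net)
  means <- attr(res, "mean_corr")
  # every miRNA represses its own targets: all mean correlations negative
  expect_true(all(means < 0))
})

test_that("mirna_sign_groups applies the inclusion threshold", {
  corr <- c(a = 0.9, b = 0.5, c = 0.2, d = -0.5, e = -0.7)
  g <- mirna_sign_groups(corr, corr)
  expect_setequal(g$EV_up, c("a", "b"))
  expect_setequal(g$EV_down, c("d", "e"))
})
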