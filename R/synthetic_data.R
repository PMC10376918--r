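#' Default RNA class vocabulary
#'
#' Ten small non-coding RNA classes used as the default vocabulary of the
#' cohort simulator. The vocabulary is configurable everywhere it is used.
#' @return character vector of length 10.
#' @export
default_rna_classes <- function() {
  c("miRNA", "tRF", "rRNA", "snoRNA", "snRNA",
    "piRNA", "lincRNA", "circRNA", "scaRNA", "misc_RNA")
}

#' Map age in months to coarse age group
#'
#' Grouping used for the age classifier: young = 2 months, middle = 6-8
#' months, old = 12-18 months.
#'
#' @param age_months integer vector of ages.
#' @param groups named list of month sets defining the groups.
#' @return character vector of group labels.
#' @export
age_group_of <- function(age_months,
                         groups = list(young = 2, middle = c(6, 8),
                                       old = c(12, 18))) {
  out <- rep(NA_character_, length(age_months))
  for (g in names(groups)) out[age_months %in% groups[[g]]] <- g
  if (anyNA(out)) {
    stop("age(s) outside the group definition: ",
         paste(unique(age_months[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort generator.
#' Defaults emulate the study design: five ages (2, 6, 8, 12, 18 months),
#' three replicates per age per fraction, ten RNA classes. Effect sizes are
#' on the scale of within-group standard deviations of log expression over
#' the whole age range.
#'
#' @param n_features_per_class features simulated per RNA class.
#' @param class_labels RNA class vocabulary.
#' @param age_groups ages in months.
#' @param replicates_per_group_per_fraction replicates per age per fraction.
#' @param linear_fraction proportion of features with a planted linear
#'   age trend (half up, half down).
#' @param nonlinear_fraction proportion with a planted pure-nonlinear
#'   (linearly orthogonal quadratic) trajectory.
#' @param discordant_fraction proportion of the linear features whose slope
#'   sign flips between the EV and fc fractions.
#' @param effect_size planted mean shift across the age range, in units of
#'   the within-group log-scale standard deviation.
#' @param dispersion negative-binomial overdispersion of the count noise
#'   (variance = mu + dispersion * mu^2).
#' @param fraction_effect optional EV-vs-fc shift in the same sd units
#'   (0 = none): each feature gets its own Gaussian fraction loading of
#'   this scale, so the effect is compositional and survives RPM
#'   normalization; lets a cohort be simulated with only a fraction
#'   effect.
#' @param nonlinear_gain amplitude multiplier of the nonlinear shape
#'   relative to the linear swing.
#' @param seed master seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_features_per_class = 50,
                              class_labels = default_rna_classes(),
                              age_groups = c(2, 6, 8, 12, 18),
                              replicates_per_group_per_fraction = 4,
                              linear_fraction = 0.3,
                              nonlinear_fraction = 0.04,
                              discordant_fraction = 0.1,
                              effect_size = 2,
                              dispersion = 0.1,
                              fraction_effect = 0,
                              nonlinear_gain = 4,
                              seed = 1L) {
  cfg <- list(n_features_per_class = n_features_per_class,
              class_labels = class_labels,
              age_groups = sort(unique(age_groups)),
              replicates_per_group_per_fraction =
                as.integer(replicates_per_group_per_fraction),
              linear_fraction = linear_fraction,
              nonlinear_fraction = nonlinear_fraction,
              discordant_fraction = discordant_fraction,
              effect_size = effect_size,
              dispersion = dispersion,
              fraction_effect = fraction_effect,
              nonlinear_gain = nonlinear_gain,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_features_per_class >= 1, length(class_labels) >= 1,
              length(age_groups) >= 2,
              replicates_per_group_per_fraction >= 1,
              linear_fraction >= 0, nonlinear_fraction >= 0,
              linear_fraction + nonlinear_fraction <= 1,
              discordant_fraction >= 0, discordant_fraction <= 1,
              effect_size >= 0, dispersion > 0)
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

# Three independent sub-seeds (design, means, noise) from the master seed,
# so fixtures stay stable when one block of the generator is edited.
derive_seeds <- function(seed, n = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Centered/scaled age covariate: spans exactly 1 over the age range.
age_covariate <- function(age_months) {
  rng <- range(age_months)
  (age_months - rng[1]) / (rng[2] - rng[1]) - 0.5
}

# Quadratic shape made exactly orthogonal (at the design level) to the
# linear age covariate, scaled to unit range: zero linear component, full
# curvature.
nonlinear_shape <- function(age_months) {
  u <- age_covariate(age_months)
  q <- stats::resid(stats::lm(I(u^2) ~ u))
  q / diff(range(q))
}

#' Simulate a synthetic two-fraction ageing cohort
#'
#' Generates a seeded count matrix with planted age trajectories: linear
#' features shift monotonically over the age range, pure-nonlinear features
#' follow a linearly orthogonal quadratic, flat features carry no signal.
#' Discordant features flip their slope sign between the EV and fc
#' fractions. Count noise is an overdispersed gamma-Poisson (negative
#' binomial) mixture. The same mouse contributes one EV and one fc sample.
#'
#' @param cfg a [simulation_config()].
#' @return a list with `expr` (counts, [expression_matrix()]), `samples`,
#'   `features` (annotation data.frames) and `truth` (list with per-feature
#'   `features`: planted_shape, sign_EV, sign_fc; per-sample `samples`:
#'   age_group).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seeds <- derive_seeds(cfg$seed, 3L)
  n_class <- length(cfg$class_labels)
  n_feat <- cfg$n_features_per_class * n_class
  ages <- cfg$age_groups
  reps <- cfg$replicates_per_group_per_fraction

  # sample sheet: fractions x ages x replicates, mice shared across fractions
  grid <- expand.grid(rep = seq_len(reps), age = ages,
                      fraction = c("EV", "fc"), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%02dm_r%d", grid$fraction, grid$age, grid$rep),
    mouse_id = sprintf("mouse_%02dm_r%d", grid$age, grid$rep),
    age_months = grid$age,
    fraction = grid$fraction,
    stringsAsFactors = FALSE)

  # planted design
  set.seed(seeds[1])
  # a zero effect size plants no trajectories at all: truth is all-flat
  n_lin <- if (cfg$effect_size > 0) round(cfg$linear_fraction * n_feat) else 0L
  n_non <- if (cfg$effect_size > 0) round(cfg$nonlinear_fraction * n_feat) else 0L
  shape <- rep("flat", n_feat)
  idx <- sample.int(n_feat)           # shapes spread randomly over classes
  lin_idx <- idx[seq_len(n_lin)]
  non_idx <- idx[n_lin + seq_len(n_non)]
  shape[lin_idx] <- rep(c("linear_up", "linear_down"), length.out = n_lin)
  shape[non_idx] <- "nonlinear"
  # curvature sign alternates (bell vs U shapes), keeping the library
  # composition stable across ages under RPM normalization
  curvature <- integer(n_feat)
  curvature[non_idx] <- rep(c(1L, -1L), length.out = n_non)
  sign_fc <- ifelse(shape == "linear_up", 1L, ifelse(shape == "linear_down", -1L, 0L))
  sign_ev <- sign_fc
  n_disc <- round(cfg$discordant_fraction * n_lin)
  if (n_disc > 0) {
    disc <- sample(lin_idx, n_disc)
    sign_ev[disc] <- -sign_ev[disc]
  }
  feature_id <- sprintf("feat_%04d", seq_len(n_feat))
  features <- data.frame(feature_id = feature_id,
                         rna_class = rep(cfg$class_labels,
                                         each = cfg$n_features_per_class),
                         stringsAsFactors = FALSE)

  # log-scale means
  set.seed(seeds[2])
  sigma <- sqrt(cfg$dispersion)       # nominal within-group log-scale sd
  log_base <- stats::rnorm(n_feat, mean = log(100), sd = 1)
  frac_load <- stats::rnorm(n_feat)   # per-feature EV-vs-fc loading
  u <- age_covariate(samples$age_months)
  q <- nonlinear_shape(ages)[match(samples$age_months, ages)]
  swing <- cfg$effect_size * sigma
  amp <- cfg$nonlinear_gain * swing
  sgn <- ifelse(samples$fraction == "EV", 1, 0)
  log_mu <- outer(log_base, rep(0, nrow(samples)), "+")
  for (j in seq_len(nrow(samples))) {
    s_j <- if (samples$fraction[j] == "EV") sign_ev else sign_fc
    log_mu[, j] <- log_base + swing * s_j * u[j] +
      amp * curvature * q[j] +
      cfg$fraction_effect * sigma * frac_load * sgn[j]
  }
  mu <- exp(log_mu)

  # gamma-Poisson counts
  set.seed(seeds[3])
  shp <- 1 / cfg$dispersion
  lambda <- matrix(stats::rgamma(length(mu), shape = shp, rate = shp / mu),
                   nrow = n_feat)
  counts <- matrix(as.double(stats::rpois(length(lambda), lambda)),
                   nrow = n_feat,
                   dimnames = list(feature_id, samples$sample_id))

  truth <- list(
    features = data.frame(feature_id = feature_id, planted_shape = shape,
                          sign_EV = sign_ev, sign_fc = sign_fc,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples$sample_id,
                         age_group = age_group_of(samples$age_months),
                         stringsAsFactors = FALSE))
  list(expr = expression_matrix(counts, "raw_counts"),
       samples = samples, features = features, truth = truth)
}

#' Simulate a matrix with planted sample groups
#'
#' A compact generator for the age-group classifier: `k` sample groups with
#' random group-specific feature profiles separated by `effect_size`
#' within-group standard deviations, plus Gaussian noise, rescaled to
#' [0, 1] by its maximum. Group 1..3 map to young/middle/old.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group.
#' @param k number of groups (default 3).
#' @param effect_size group separation in within-group sd units.
#' @param noise_sd within-group standard deviation.
#' @param seed seed.
#' @return list with `D` (matrix in \[0, 1\], features x samples) and
#'   `truth` (character group labels per sample).
#' @export
simulate_group_matrix <- function(n_features = 200, n_per_group = 10, k = 3,
                                  effect_size = 1.5, noise_sd = 1, seed = 1L) {
  stopifnot(n_features >= 1, n_per_group >= 1, k >= 2)
  set.seed(seed)
  labels <- rep(seq_len(k), each = n_per_group)
  base <- stats::runif(n_features, 2, 6)
  profile <- matrix(stats::rnorm(n_features * k, sd = effect_size * noise_sd),
                    n_features, k)
  m <- base + profile[, labels] +
    matrix(stats::rnorm(n_features * length(labels), sd = noise_sd),
           n_features)
  m <- pmax(m, 0)
  dimnames(m) <- list(sprintf("feat_%03d", seq_len(n_features)),
                      sprintf("s%02d", seq_along(labels)))
  group_names <- c("young", "middle", "old", sprintf("group%d", seq_len(max(0, k - 3)) + 3))
  list(D = m / max(m), truth = group_names[labels])
}

#' Simulate a miRNA-target atlas with planted repression
#'
#' Generates a miRNA-to-gene edge table with evidence levels, per-tissue
#' gene expression-by-age tables, and a miRNA expression-by-age table.
#' miRNAs carry planted age slopes (half up, half down); each gene's age
#' trend is minus `repression_strength` times the summed slopes of its
#' strong-evidence regulators, plus noise, so planted repression makes
#' targets of age-increasing miRNAs decrease with age.
#'
#' @param n_mirnas,n_genes,n_tissues positive counts.
#' @param repression_strength non-negative repression coefficient.
#' @param seed seed.
#' @param noise_sd sd of the additive expression noise.
#' @param ages atlas ages in months (>= 3 values).
#' @param prop_strong probability an edge is strong evidence.
#' @return list with `edges` (mirna_id, gene_id, evidence), `tissues`
#'   (named list of gene x age matrices), `mirna_expr` (miRNA x age
#'   matrix), `ages`, and `truth` (mirna_slope, gene_slope).
#' @export
simulate_target_atlas <- function(n_mirnas = 10, n_genes = 60, n_tissues = 4,
                                  repression_strength = 1, seed = 1L,
                                  noise_sd = 0.1,
                                  ages = c(3, 9, 15, 21, 27),
                                  prop_strong = 0.7) {
  stopifnot(n_mirnas >= 1, n_genes >= 1, n_tissues >= 1,
            repression_strength >= 0, length(ages) >= 3)
  if (n_genes < n_mirnas) {
    stop("n_genes must be at least n_mirnas so every miRNA can have targets",
         call. = FALSE)
  }
  set.seed(seed)
  mirna_id <- sprintf("miR-%02d", seq_len(n_mirnas))
  gene_id <- sprintf("Gene%03d", seq_len(n_genes))
  mirna_slope <- rep(c(1, -1), length.out = n_mirnas)

  # regulators per gene: most genes have a single planted regulator so the
  # group-level repression signal is not washed out by mixed-sign genes;
  # the tail of the distribution still produces multi-miRNA hub genes
  k <- sample(1:4, n_genes, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  edges <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    regs <- sample(n_mirnas, min(k[g], n_mirnas))
    data.frame(mirna_id = mirna_id[regs], gene_id = gene_id[g],
               evidence = sample(c("strong", "weak"), length(regs),
                                 replace = TRUE,
                                 prob = c(prop_strong, 1 - prop_strong)),
               stringsAsFactors = FALSE)
  }))
  strong <- edges[edges$evidence == "strong", ]
  gene_slope <- vapply(gene_id, function(g) {
    regs <- strong$mirna_id[strong$gene_id == g]
    -repression_strength * sum(mirna_slope[match(regs, mirna_id)])
  }, numeric(1))

  u <- age_covariate(ages)
  tissues <- lapply(seq_len(n_tissues), function(t) {
    base <- stats::runif(n_genes, 4, 8)
    m <- outer(gene_slope, u) + base +
      matrix(stats::rnorm(n_genes * length(ages), sd = noise_sd), n_genes)
    dimnames(m) <- list(gene_id, as.character(ages))
    m
  })
  names(tissues) <- sprintf("tissue_%02d", seq_len(n_tissues))
  mirna_expr <- outer(mirna_slope, u) + stats::runif(n_mirnas, 4, 8) +
    matrix(stats::rnorm(n_mirnas * length(ages), sd = noise_sd), n_mirnas)
  dimnames(mirna_expr) <- list(mirna_id, as.character(ages))

  list(edges = edges, tissues = tissues, mirna_expr = mirna_expr, ages = ages,
       truth = list(mirna_slope = stats::setNames(mirna_slope, mirna_id),
                    gene_slope = stats::setNames(gene_slope, gene_id)))
}

#' Simulate a qPCR Ct table
#'
#' Two groups (young/old), two endogenous control assays held at
#' `control_ct`, and one target assay per entry of `true_log2fc` whose Ct
#' drops by the planted log2 fold change in the old group (one PCR cycle =
#' one doubling).
#'
#' @param n_young,n_old samples per group (>= 1).
#' @param true_log2fc named numeric vector: planted log2 fold change
#'   (old vs young) per target assay.
#' @param control_ct baseline Ct of the controls.
#' @param noise_sd technical noise sd in cycles (>= 0).
#' @param seed seed.
#' @param control_assays ids of the two endogenous controls.
#' @return data.frame with columns sample_id, group, assay_id, ct.
#' @export
simulate_qpcr <- function(n_young = 4, n_old = 2,
                          true_log2fc = c(`miR-29a-3p` = 1.5),
                          control_ct = 25, noise_sd = 0, seed = 1L,
                          control_assays = c("miR-191a", "let-7a")) {
  stopifnot(n_young >= 1, n_old >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(names(true_log2fc)) || any(!nzchar(names(true_log2fc)))) {
    stop("true_log2fc must be a named vector of target assays", call. = FALSE)
  }
  set.seed(seed)
  sample_id <- c(sprintf("young_%d", seq_len(n_young)),
                 sprintf("old_%d", seq_len(n_old)))
  group <- rep(c("young", "old"), c(n_young, n_old))
  assays <- c(control_assays, names(true_log2fc))
  rows <- expand.grid(sample_id = sample_id, assay_id = assays,
                      stringsAsFactors = FALSE)
  rows$group <- group[match(rows$sample_id, sample_id)]
  is_old <- rows$group == "old"
  is_ctrl <- rows$assay_id %in% control_assays
  lfc <- ifelse(is_ctrl, 0, true_log2fc[rows$assay_id])
  rows$ct <- control_ct - lfc * is_old +
    stats::rnorm(nrow(rows), sd = noise_sd)
  rows[, c("sample_id", "group", "assay_id", "ct")]
}
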