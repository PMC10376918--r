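#' Pipeline configuration
#'
#' Collects input paths, per-stage parameters and the master seed of an
#' end-to-end run. Input files are the fixture set written by
#' [generate_fixtures()] (expression matrix, sample and feature sheets,
#' optional target-atlas and Ct tables).
#'
#' @param input_dir directory holding the input TSVs.
#' @param out_dir output directory (created if missing).
#' @param age_groups named list of disjoint month sets defining
#'   young/middle/old.
#' @param min_rpm expression filter threshold.
#' @param spline_df spline degrees of freedom of the nonlinearity screen.
#' @param nonlinear_threshold residual cut-off of the screen.
#' @param nmf_restarts restarts of the NMF classifier.
#' @param cut_divisor dendrogram cut divisor.
#' @param n_permutations permutations of the mean-shift and enrichment
#'   tests.
#' @param hub_threshold hub in-degree threshold.
#' @param enrichment_magnitude orders-of-magnitude contrast threshold.
#' @param min_class_features classes smaller than this are skipped in the
#'   per-class NMF runs.
#' @param seed master seed.
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            age_groups = list(young = 2, middle = c(6, 8),
                                              old = c(12, 18)),
                            min_rpm = 5, spline_df = 7,
                            nonlinear_threshold = 0.15,
                            nmf_restarts = 10L, cut_divisor = 1.25,
                            n_permutations = 200L, hub_threshold = 3L,
                            enrichment_magnitude = 3,
                            min_class_features = 10L, seed = 1L) {
  months <- unlist(age_groups, use.names = FALSE)
  if (anyDuplicated(months)) stop("age group month sets must be disjoint",
                                  call. = FALSE)
  stopifnot(min_rpm >= 0, spline_df >= 2, nonlinear_threshold > 0,
            nmf_restarts >= 1, cut_divisor >= 1, n_permutations >= 1,
            hub_threshold >= 1, enrichment_magnitude > 0)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 age_groups = age_groups, min_rpm = min_rpm,
                 spline_df = spline_df,
                 nonlinear_threshold = nonlinear_threshold,
                 nmf_restarts = as.integer(nmf_restarts),
                 cut_divisor = cut_divisor,
                 n_permutations = as.integer(n_permutations),
                 hub_threshold = as.integer(hub_threshold),
                 enrichment_magnitude = enrichment_magnitude,
                 min_class_features = as.integer(min_class_features),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a complete synthetic fixture set
#'
#' Generates an internally consistent input directory for the pipeline:
#' expression matrix, sample and feature sheets, simulation truth, a
#' miRNA-target atlas (edge table, per-tissue expression-by-age tables,
#' miRNA expression-by-age table) and a qPCR Ct table.
#'
#' @param preset `"tiny"` (fast smoke runs), `"default"` (simulation
#'   defaults) or `"stress"` (larger cohort).
#' @param seed master seed.
#' @param out_dir output directory, created if missing.
#' @return the output directory path, invisibly; files are all TSV.
#' @export
generate_fixtures <- function(preset = c("tiny", "default", "stress"),
                              seed = 1L, out_dir = tempfile("fixtures_")) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- switch(preset,
    tiny = simulation_config(n_features_per_class = 5, seed = seed),
    default = simulation_config(seed = seed),
    stress = simulation_config(n_features_per_class = 200, seed = seed))
  sim <- simulate_cohort(cfg)
  write_expression(sim$expr, file.path(out_dir, "counts.tsv"))
  write_tsv(sim$samples, file.path(out_dir, "samples.tsv"))
  write_tsv(sim$features, file.path(out_dir, "features.tsv"))
  write_tsv(sim$truth$features, file.path(out_dir, "truth_features.tsv"))
  write_tsv(sim$truth$samples, file.path(out_dir, "truth_samples.tsv"))

  atlas <- simulate_target_atlas(
    n_mirnas = if (preset == "tiny") 6 else 12,
    n_genes = if (preset == "tiny") 30 else 80,
    n_tissues = if (preset == "tiny") 2 else 4,
    repression_strength = 1, seed = seed)
  write_tsv(atlas$edges, file.path(out_dir, "target_edges.tsv"))
  for (ts in names(atlas$tissues)) {
    df <- data.frame(gene_id = rownames(atlas$tissues[[ts]]),
                     atlas$tissues[[ts]], check.names = FALSE)
    write_tsv(df, file.path(out_dir, paste0("tissue_", ts, ".tsv")))
  }
  write_tsv(data.frame(mirna_id = rownames(atlas$mirna_expr),
                       atlas$mirna_expr, check.names = FALSE),
            file.path(out_dir, "mirna_by_age.tsv"))

  ct <- simulate_qpcr(n_young = 4, n_old = 2,
                      true_log2fc = c(`miR-29a-3p` = 1.5, `miR-29b-3p` = 1.0),
                      noise_sd = 0.1, seed = seed)
  write_tsv(ct, file.path(out_dir, "qpcr_ct.tsv"))
  invisible(out_dir)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order over a fixture directory:
#' read/validate, RPM normalization and expression filtering, per-feature
#' trajectory statistics with the nonlinearity screen, cross-fraction
#' quadrant concordance and the mean-shift permutation test, per-class
#' NMF age classification, per-fraction clustering with cross-fraction
#' mapping, variance attribution, running-sum enrichment of the RNA
#' classes over the age-ranked feature list, target-network concordance
#' and delta-delta-Ct quantification (the latter two when their inputs
#' exist). Every output file is listed in the returned manifest with an
#' MD5 checksum; reruns with identical config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to execute and write (default: all). The io and
#'   trajectory stages always run, as every later stage depends on them.
#' @return data.frame manifest (stage, file, md5), written to
#'   `manifest.tsv` in the output directory as well.
#' @export
run_pipeline <- function(config,
                         stages = c("io", "trajectory", "nmf", "clustering",
                                    "variance", "enrichment", "network",
                                    "qpcr")) {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  wanted <- function(s) s %in% stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, df, name) {
    if (!stage %in% c(stages, "io", "trajectory")) return(invisible())
    path <- write_tsv(df, file.path(config$out_dir, name))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }

  # io
  dat <- read_expression(file.path(config$input_dir, "counts.tsv"),
                         file.path(config$input_dir, "samples.tsv"),
                         file.path(config$input_dir, "features.tsv"))
  rpm <- normalize_rpm(dat$expr)
  filt <- filter_expressed(rpm, min_rpm = config$min_rpm)
  emit("io", data.frame(metric = c("n_features", "n_expressed", "n_samples"),
                        value = c(nrow(dat$expr$values), nrow(filt$values),
                                  ncol(filt$values))), "io_summary.tsv")

  samples <- dat$samples
  ages <- samples$age_months[match(filt$sample_ids, samples$sample_id)]
  frac <- samples$fraction[match(filt$sample_ids, samples$sample_id)]

  # trajectory
  stats <- trajectory_stats(filt, samples)
  stats_cls <- do.call(rbind, lapply(split(stats, stats$fraction),
    classify_nonlinear, df = config$spline_df,
    threshold = config$nonlinear_threshold))
  emit("trajectory", stats_cls, "trajectory_stats.tsv")

  ev_stats <- stats[stats$fraction == "EV", ]
  fc_stats <- stats[stats$fraction == "fc", ]
  common <- intersect(ev_stats$feature_id, fc_stats$feature_id)
  quad <- quadrant_concordance(
    ev_stats$pearson_r[match(common, ev_stats$feature_id)],
    fc_stats$pearson_r[match(common, fc_stats$feature_id)])
  emit("trajectory",
       data.frame(quadrant = names(quad$counts), count = as.integer(quad$counts),
                  fraction = as.numeric(quad$fractions),
                  n_excluded = quad$n_excluded, p_value = quad$p_value),
       "quadrants.tsv")
  shift <- mean_shift_permutation_test(
    filt[, frac == "EV"], filt[, frac == "fc"],
    ages[frac == "EV"], ages[frac == "fc"],
    n_permutations = config$n_permutations, seed = config$seed)
  emit("trajectory",
       data.frame(observed_mean_EV = shift$observed_mean_EV,
                  observed_mean_fc = shift$observed_mean_fc,
                  observed_difference = shift$observed_difference,
                  p_value = shift$p_value,
                  n_permutations = shift$n_permutations, seed = shift$seed),
       "mean_shift.tsv")

  # nmf: one run per RNA class x fraction with enough features
  cls <- dat$features$rna_class[match(filt$feature_ids,
                                      dat$features$feature_id)]
  truth_all <- age_group_of_months(ages, config$age_groups)
  nmf_rows <- list()
  if (wanted("nmf")) for (cl in unique(cls)) {
    if (sum(cls == cl) < config$min_class_features) next
    for (fr in unique(frac)) {
      D <- filt$values[cls == cl, frac == fr, drop = FALSE]
      if (max(D) <= 0) next
      fit <- fit_age_nmf(normalize_max(D), k = length(config$age_groups),
                         n_restarts = config$nmf_restarts, seed = config$seed)
      sc <- classify_and_score(fit, truth_all[frac == fr],
                               group_levels = names(config$age_groups))
      nmf_rows[[paste(cl, fr)]] <- data.frame(
        rna_class = cl, fraction = fr, accuracy = sc$accuracy,
        objective = fit$objective, seed = config$seed,
        stringsAsFactors = FALSE)
    }
  }
  if (wanted("nmf") && !length(nmf_rows)) {
    # no class reaches min_class_features: run once on the full matrix
    for (fr in unique(frac)) {
      D <- filt$values[, frac == fr, drop = FALSE]
      fit <- fit_age_nmf(normalize_max(D), k = length(config$age_groups),
                         n_restarts = config$nmf_restarts, seed = config$seed)
      sc <- classify_and_score(fit, truth_all[frac == fr],
                               group_levels = names(config$age_groups))
      nmf_rows[[fr]] <- data.frame(
        rna_class = "all", fraction = fr, accuracy = sc$accuracy,
        objective = fit$objective, seed = config$seed,
        stringsAsFactors = FALSE)
    }
  }
  if (wanted("nmf")) emit("nmf", do.call(rbind, nmf_rows), "nmf_summary.tsv")

  # clustering
  if (wanted("clustering")) {
    cl_ev <- cluster_features(filt[, frac == "EV"], min_rpm = config$min_rpm,
                              cut_divisor = config$cut_divisor)
    cl_fc <- cluster_features(filt[, frac == "fc"], min_rpm = config$min_rpm,
                              cut_divisor = config$cut_divisor)
    smap <- summarize_and_map(cl_ev, cl_fc, stats)
    emit("clustering", rbind(cbind(fraction = "EV", cl_ev$assignments),
                             cbind(fraction = "fc", cl_fc$assignments)),
         "cluster_assignments.tsv")
    emit("clustering", rbind(cbind(fraction = "EV", smap$summary_EV),
                             cbind(fraction = "fc", smap$summary_fc)),
         "cluster_summary.tsv")
    ov <- as.data.frame(as.table(smap$overlap), stringsAsFactors = FALSE)
    names(ov) <- c("cluster_EV", "cluster_fc", "shared_features")
    emit("clustering", ov, "cluster_overlap.tsv")
  }

  # variance attribution
  if (wanted("variance")) {
    va <- variance_attribution(filt, samples)
    emit("variance", data.frame(factor = names(va$proportions),
                                proportion = as.numeric(va$proportions)),
         "variance_attribution.tsv")
  }

  # enrichment of the RNA classes over the age-ranked feature list
  if (wanted("enrichment")) {
  r_ev <- ev_stats$pearson_r
  names(r_ev) <- ev_stats$feature_id
  ranked <- names(sort(r_ev[is.finite(r_ev)], decreasing = TRUE))
  cats <- split(dat$features$feature_id, dat$features$rna_class)
  cats <- cats[vapply(cats, function(m) any(m %in% ranked), logical(1))]
  enr <- set_enrichment(ranked, cats,
                        n_permutations = config$n_permutations,
                        seed = config$seed, keep_curves = FALSE)
  emit("enrichment", as.data.frame(enr), "enrichment_EV.tsv")
  }

  # target network (optional inputs)
  edge_path <- file.path(config$input_dir, "target_edges.tsv")
  if (wanted("network") && file.exists(edge_path)) {
    edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
    mirna_path <- file.path(config$input_dir, "mirna_by_age.tsv")
    mexpr <- utils::read.delim(mirna_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
    mm <- as.matrix(mexpr[, -1, drop = FALSE])
    rownames(mm) <- mexpr[[1]]
    m_ages <- as.numeric(colnames(mm))
    mcorr <- apply(mm, 1L, function(v) stats::cor(v, m_ages))
    net <- build_network(edges, mcorr, hub_threshold = config$hub_threshold)
    tissue_files <- list.files(config$input_dir, "^tissue_.*\\.tsv$",
                               full.names = TRUE)
    tissues <- lapply(tissue_files, function(p) {
      df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df[[1]]; m
    })
    names(tissues) <- sub("\\.tsv$", "", sub("^tissue_", "", basename(tissue_files)))
    groups <- mirna_sign_groups(mcorr, mcorr)[c("EV_up", "EV_down")]
    conc <- target_age_concordance(net, tissues, groups)
    emit("network", as.data.frame(conc), "target_concordance.tsv")
    emit("network", net$edges, "network_edges.tsv")
  }

  # qPCR (optional input)
  ct_path <- file.path(config$input_dir, "qpcr_ct.tsv")
  if (wanted("qpcr") && file.exists(ct_path)) {
    ct <- utils::read.delim(ct_path, stringsAsFactors = FALSE)
    targets <- setdiff(unique(ct$assay_id), c("miR-191a", "let-7a"))
    qp <- do.call(rbind, lapply(targets, function(a) {
      res <- delta_delta_ct(ct, a)
      data.frame(assay = a, log2fc = res$log2fc,
                 n_young = res$n_reference, n_old = res$n_comparison,
                 stringsAsFactors = FALSE)
    }))
    emit("qpcr", qp, "qpcr_log2fc.tsv")
  }

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  manifest
}

# age -> group label under a configurable grouping
age_group_of_months <- function(age_months, age_groups) {
  age_group_of(age_months, groups = age_groups)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a fixture set), `run` (all stages), and the
#' single-stage verbs `trajectory`, `nmf`, `cluster`, `variance`,
#' `enrich`, `network`, `qpcr`, which execute the pipeline up to and
#' including that stage but write only its outputs. Example:
#' `Rscript -e 'evaging::evaging_cli()' simulate --preset tiny --seed 1 --out fx`
#' then `... run --in fx --seed 1 --out results`.
#'
#' @param args character vector of CLI arguments (default: command line).
#' @return exit status 0 invisibly; called for its side effects.
#' @export
evaging_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verb_stage <- c(trajectory = "trajectory", nmf = "nmf",
                  cluster = "clustering", variance = "variance",
                  enrich = "enrichment", network = "network", qpcr = "qpcr")
  usage <- paste(
    "usage: evaging_cli <simulate|run|trajectory|nmf|cluster|variance|",
    "enrich|network|qpcr> [--preset tiny|default|stress] [--in DIR]",
    "[--out DIR] [--seed INT]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  verb <- args[[1]]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[[i + 1L]] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", file.path(tempdir(), "evaging_out"))
  if (verb == "simulate") {
    generate_fixtures(opt("--preset", "tiny"), seed = seed, out_dir = out)
    message("fixtures written to ", out)
  } else if (verb == "run" || verb %in% names(verb_stage)) {
    input <- opt("--in", ".")
    cfg <- pipeline_config(input_dir = input, out_dir = out, seed = seed)
    mf <- if (verb == "run") run_pipeline(cfg) else
      run_pipeline(cfg, stages = verb_stage[[verb]])
    message("pipeline complete: ", nrow(mf), " output file(s) in ", out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
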