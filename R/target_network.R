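#' Build a strong-evidence miRNA-target network
#'
#' Filters a miRNA-to-gene edge table by evidence level, drops miRNAs
#' lacking an age-correlation annotation (with a warning), and annotates
#' hub genes targeted by at least `hub_threshold` distinct miRNAs.
#'
#' @param edges data.frame with columns mirna_id, gene_id, evidence
#'   (`"strong"`/`"weak"`).
#' @param mirna_age_corr named numeric vector: age correlation per miRNA.
#' @param evidence_filter evidence level kept (default "strong").
#' @param hub_threshold minimum in-degree for hub genes (default 3).
#' @return list of class `TargetNetwork`: `edges`, `mirnas`, `genes`,
#'   `mirna_age_corr`, `hub_genes`, `in_degree`. An empty post-filter
#'   network is returned with a warning, not an error.
#' @export
build_network <- function(edges, mirna_age_corr,
                          evidence_filter = "strong", hub_threshold = 3L) {
  need <- c("mirna_id", "gene_id", "evidence")
  if (!all(need %in% names(edges))) {
    stop("edge table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  e <- edges[edges$evidence %in% evidence_filter, , drop = FALSE]
  missing <- setdiff(unique(e$mirna_id), names(mirna_age_corr))
  if (length(missing)) {
    warning("dropping miRNA(s) without age correlation: ",
            paste(utils::head(missing, 5), collapse = ", "))
    e <- e[e$mirna_id %in% names(mirna_age_corr), , drop = FALSE]
  }
  e <- unique(e[, need])
  if (!nrow(e)) warning("network is empty after filtering")
  deg <- table(e$gene_id)
  hubs <- names(deg)[deg >= hub_threshold]
  structure(list(edges = e, mirnas = unique(e$mirna_id),
                 genes = unique(e$gene_id),
                 mirna_age_corr = mirna_age_corr[unique(e$mirna_id)],
                 hub_genes = hubs,
                 in_degree = stats::setNames(as.integer(deg), names(deg))),
            class = "TargetNetwork")
}

# Pearson age correlation per gene over a gene x age matrix
gene_age_correlations <- function(expr_by_age, ages) {
  apply(expr_by_age, 1L, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, ages)
  })
}

#' Target-gene age concordance across tissues
#'
#' For each tissue and each miRNA sign group (e.g. EV-up, EV-down, fc-up,
#' fc-down): computes the Pearson age correlation of every target gene of
#' the group's miRNAs and averages over the union of those targets. Under
#' miRNA-mediated repression, targets of age-increasing miRNAs are
#' expected to decrease with age and vice versa.
#'
#' @param net a `TargetNetwork`.
#' @param tissue_expression named list of gene x age matrices (column
#'   names = ages in months, >= 3 ages).
#' @param mirna_groups named list of miRNA id vectors (the sign groups).
#' @return data.frame of class `ConcordanceTable`: tissue, group,
#'   mean_target_corr (`NA` when undefined), n_targets.
#' @export
target_age_concordance <- function(net, tissue_expression, mirna_groups) {
  stopifnot(inherits(net, "TargetNetwork"))
  rows <- list()
  for (ts in names(tissue_expression)) {
    m <- tissue_expression[[ts]]
    ages <- as.numeric(colnames(m))
    if (length(ages) < 3) stop("tissue ", ts, " has fewer than 3 ages",
                               call. = FALSE)
    gcor <- gene_age_correlations(m, ages)
    for (grp in names(mirna_groups)) {
      mirs <- intersect(mirna_groups[[grp]], net$mirnas)
      targets <- unique(net$edges$gene_id[net$edges$mirna_id %in% mirs])
      targets <- intersect(targets, rownames(m))
      vals <- gcor[targets]
      vals <- vals[is.finite(vals)]
      rows[[paste(ts, grp)]] <- data.frame(
        tissue = ts, group = grp,
        mean_target_corr = if (length(vals)) mean(vals) else NA_real_,
        n_targets = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ConcordanceTable", class(out))
  out
}

#' Direct miRNA-target expression correlation
#'
#' Correlates each network miRNA with each of its target genes across the
#' samples shared between the two expression tables, and orders miRNAs by
#' ascending mean target correlation, so the most consistent repressors
#' come first.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param gene_expr gene x sample matrix.
#' @param net a `TargetNetwork`.
#' @return list, one element per miRNA in ascending-mean order, each a
#'   data.frame (gene_id, correlation); mean correlations in the
#'   `"mean_corr"` attribute.
#' @export
direct_target_correlation <- function(mirna_expr, gene_expr, net) {
  stopifnot(inherits(net, "TargetNetwork"))
  shared <- intersect(colnames(mirna_expr), colnames(gene_expr))
  if (length(shared) < 3) stop("need at least 3 shared samples", call. = FALSE)
  out <- list()
  for (mir in intersect(net$mirnas, rownames(mirna_expr))) {
    targets <- unique(net$edges$gene_id[net$edges$mirna_id == mir])
    targets <- intersect(targets, rownames(gene_expr))
    if (!length(targets)) next
    r <- vapply(targets, function(g) {
      stats::cor(mirna_expr[mir, shared], gene_expr[g, shared])
    }, numeric(1))
    out[[mir]] <- data.frame(gene_id = targets, correlation = r,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(structure(list(), mean_corr = numeric(0)))
  means <- vapply(out, function(d) mean(d$correlation), numeric(1))
  out <- out[order(means)]
  attr(out, "mean_corr") <- sort(means)
  out
}

#' Split miRNAs into age-correlation sign groups
#'
#' Convenience grouping for [target_age_concordance()]: per fraction, the
#' miRNAs with age correlation at or above `threshold` (up) and at or
#' below -`threshold` (down).
#'
#' @param corr_EV,corr_fc named correlation vectors per fraction.
#' @param threshold inclusion threshold on |r| (default 0.5, the nominal
#'   significance landmark).
#' @return named list: EV_up, EV_down, fc_up, fc_down.
#' @export
mirna_sign_groups <- function(corr_EV, corr_fc, threshold = 0.5) {
  list(EV_up = names(corr_EV)[corr_EV >= threshold],
       EV_down = names(corr_EV)[corr_EV <= -threshold],
       fc_up = names(corr_fc)[corr_fc >= threshold],
       fc_down = names(corr_fc)[corr_fc <= -threshold])
}
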