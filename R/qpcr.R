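#' Delta-delta-Ct relative quantification
#'
#' Computes the log2 fold change of a target assay between two groups from
#' a long-format Ct table, normalizing each sample against the arithmetic
#' mean of two conjoint endogenous control assays (equivalent to the
#' geometric mean of the linear quantities):
#' per sample dCt = Ct_target - mean(Ct_control1, Ct_control2);
#' ddCt = mean dCt(comparison) - mean dCt(reference); log2FC = -ddCt.
#' Samples missing a control or target value are excluded with a warning.
#'
#' @param table data.frame with columns sample_id, group, assay_id, ct.
#' @param target_assay target assay id.
#' @param control_assays character vector of two endogenous control ids.
#' @param reference_group group used as baseline (default "young").
#' @return list of class `DeltaDeltaCt`: `log2fc`, `ddct`, `delta_ct`
#'   (per-sample data.frame), `n_reference`, `n_comparison`,
#'   `reference_group`, `comparison_group`.
#' @export
delta_delta_ct <- function(table, target_assay,
                           control_assays = c("miR-191a", "let-7a"),
                           reference_group = "young") {
  need <- c("sample_id", "group", "assay_id", "ct")
  if (!all(need %in% names(table))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(control_assays) != 2) stop("exactly two control assays required",
                                        call. = FALSE)
  if (any(!is.finite(table$ct))) stop("Ct values must be finite", call. = FALSE)
  groups <- unique(table$group)
  if (!reference_group %in% groups) stop("reference group absent from table",
                                         call. = FALSE)
  comparison_group <- setdiff(groups, reference_group)
  if (length(comparison_group) != 1) {
    stop("Ct table must contain exactly two groups", call. = FALSE)
  }
  rows <- list()
  excluded <- character(0)
  for (s in unique(table$sample_id)) {
    sub <- table[table$sample_id == s, ]
    ct_t <- sub$ct[sub$assay_id == target_assay]
    ct_c <- vapply(control_assays,
                   function(a) if (any(sub$assay_id == a))
                     mean(sub$ct[sub$assay_id == a]) else NA_real_,
                   numeric(1))
    if (length(ct_t) != 1 || anyNA(ct_c)) {
      excluded <- c(excluded, s)
      next
    }
    rows[[s]] <- data.frame(sample_id = s, group = sub$group[1],
                            delta_ct = ct_t - mean(ct_c),
                            stringsAsFactors = FALSE)
  }
  if (length(excluded)) {
    warning("excluding sample(s) with missing target/control Ct: ",
            paste(excluded, collapse = ", "))
  }
  dct <- do.call(rbind, rows)
  n_ref <- sum(dct$group == reference_group)
  n_cmp <- sum(dct$group == comparison_group)
  if (!n_ref || !n_cmp) stop("a group is empty after exclusions", call. = FALSE)
  ddct <- mean(dct$delta_ct[dct$group == comparison_group]) -
    mean(dct$delta_ct[dct$group == reference_group])
  structure(list(log2fc = -ddct, ddct = ddct, delta_ct = dct,
                 n_reference = n_ref, n_comparison = n_cmp,
                 reference_group = reference_group,
                 comparison_group = comparison_group),
            class = "DeltaDeltaCt")
}
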