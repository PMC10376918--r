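#' Read gene/miRNA sets in GMT format
#'
#' One set per line: set id, description, then member ids, tab separated.
#'
#' @param path GMT file path.
#' @return named list of character member vectors; descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2L]] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

# unweighted Kolmogorov-Smirnov-style running sum over a 0/1 hit vector:
# +(N-K) at every hit, -K at every miss; always terminates at exactly 0
running_sum <- function(hits) {
  n <- length(hits)
  k <- sum(hits)
  cumsum(ifelse(hits, n - k, -k))
}

#' Running-sum set enrichment over a ranked miRNA list
#'
#' For each category, walks down the ranked list adding (N - K) at every
#' member ("hit") and subtracting K at every non-member, where N is the
#' list length and K the category size in the list; the enrichment score
#' is the maximum absolute deviation of this running sum, which by
#' construction terminates at exactly 0. Significance is assessed against
#' a permutation null that shuffles category membership over list
#' positions; p-values carry the add-one correction and all categories are
#' reported regardless of p (nominal p-value threshold 1), with
#' Benjamini-Hochberg adjustment across categories.
#'
#' @param ranked character vector of feature ids, ordered by decreasing
#'   age correlation (no duplicates).
#' @param categories named list of character member sets; members absent
#'   from the ranked list are dropped (categories left empty are dropped
#'   with a warning).
#' @param n_permutations permutations per category (default 1000).
#' @param seed RNG seed.
#' @param keep_curves store each observed running-sum curve (default TRUE).
#' @return data.frame of class `EnrichmentResult`: category, K, N, es,
#'   p_value, q_value; curves in the `"curves"` attribute.
#' @export
set_enrichment <- function(ranked, categories, n_permutations = 1000L,
                           seed = 1L, keep_curves = TRUE) {
  if (!length(ranked)) stop("empty ranked list", call. = FALSE)
  if (!length(categories)) stop("empty category table", call. = FALSE)
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates",
                                  call. = FALSE)
  n <- length(ranked)
  keep <- vapply(categories, function(m) sum(ranked %in% m) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " categor(ies) with no member in the list")
    categories <- categories[keep]
  }
  if (!length(categories)) stop("no category overlaps the ranked list",
                                call. = FALSE)
  set.seed(seed)
  curves <- list()
  rows <- lapply(names(categories), function(id) {
    hits <- ranked %in% categories[[id]]
    k <- sum(hits)
    rs <- running_sum(hits)
    es <- max(abs(rs))
    null_es <- vapply(seq_len(n_permutations), function(b) {
      h <- logical(n)
      h[sample.int(n, k)] <- TRUE
      max(abs(running_sum(h)))
    }, numeric(1))
    if (keep_curves) curves[[id]] <<- rs
    data.frame(category = id, K = k, N = n, es = es,
               p_value = (sum(null_es >= es) + 1) / (n_permutations + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "curves") <- curves
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Contrast enrichment significance between fractions
#'
#' Flags categories whose nominal enrichment p-values differ by at least
#' `magnitude` orders of magnitude between the EV and fc fractions
#' (EV-specific when p_fc / p_EV >= 10^magnitude and vice versa), and
#' lists categories significant after BH in both fractions.
#'
#' @param results_EV,results_fc `EnrichmentResult` data.frames over the
#'   same category universe (categories present in only one are excluded
#'   with a warning).
#' @param magnitude orders-of-magnitude threshold (default 3).
#' @param alpha BH significance level for the shared list (default 0.05).
#' @return list with `table` (category, p_EV, p_fc, log10_ratio, flag) and
#'   `shared_significant` (character vector).
#' @export
fraction_contrast <- function(results_EV, results_fc, magnitude = 3,
                              alpha = 0.05) {
  shared <- intersect(results_EV$category, results_fc$category)
  only <- c(setdiff(results_EV$category, shared),
            setdiff(results_fc$category, shared))
  if (length(only)) {
    warning("excluding categor(ies) present in one fraction only: ",
            paste(utils::head(only, 5), collapse = ", "))
  }
  if (!length(shared)) stop("no shared categories", call. = FALSE)
  p_ev <- results_EV$p_value[match(shared, results_EV$category)]
  p_fc <- results_fc$p_value[match(shared, results_fc$category)]
  ratio <- log10(p_fc / p_ev)        # positive: stronger in EV
  flag <- ifelse(ratio >= magnitude, "EV_specific",
                 ifelse(-ratio >= magnitude, "fc_specific", "none"))
  q_ev <- results_EV$q_value[match(shared, results_EV$category)]
  q_fc <- results_fc$q_value[match(shared, results_fc$category)]
  list(table = data.frame(category = shared, p_EV = p_ev, p_fc = p_fc,
                          log10_ratio = ratio, flag = flag,
                          stringsAsFactors = FALSE),
       shared_significant = shared[q_ev <= alpha & q_fc <= alpha])
}
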