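#' Cluster features on scaled expression
#'
#' Applies the expression filter, standardizes each retained feature to
#' mean 0 and variance 1 across samples (population variance), builds the
#' Euclidean distance matrix over features, runs agglomerative hierarchical
#' clustering with complete linkage, and extracts flat clusters by cutting
#' the dendrogram at (maximal merge height) / `cut_divisor`.
#'
#' @param x an `ExpressionMatrix` in RPM units.
#' @param min_rpm expression filter threshold (default 5, >= 1 sample).
#' @param cut_divisor dendrogram cut divisor (default 1.25: cut at
#'   h_max / 1.25 = 0.8 h_max).
#' @param linkage agglomeration method (default "complete").
#' @return list of class `ClusterResult`: `assignments` (data.frame
#'   feature_id, cluster), `h_max`, `cut_height`, `n_clusters`,
#'   `dropped` (zero-variance feature ids, excluded with a warning).
#' @export
cluster_features <- function(x, min_rpm = 5, cut_divisor = 1.25,
                             linkage = "complete") {
  validate_expression_matrix(x)
  xf <- filter_expressed(x, min_rpm = min_rpm)
  v <- xf$values
  sds <- apply(v, 1L, stats::sd)
  dropped <- rownames(v)[sds == 0]
  if (length(dropped)) {
    warning("excluding ", length(dropped), " zero-variance feature(s)")
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("need at least 2 variable features", call. = FALSE)
  z <- zscore_rows(v)
  hc <- stats::hclust(stats::dist(z), method = linkage)
  h_max <- max(hc$height)
  cut_h <- h_max / cut_divisor
  cl <- stats::cutree(hc, h = cut_h)
  structure(list(assignments = data.frame(feature_id = rownames(v),
                                          cluster = as.integer(cl),
                                          stringsAsFactors = FALSE),
                 h_max = h_max, cut_height = cut_h,
                 n_clusters = length(unique(cl)), dropped = dropped),
            class = "ClusterResult")
}

# row z-score with population variance (ddof 0)
zscore_rows <- function(v) {
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  (v - mu) / sd_pop
}

#' Summarize clusters and map them across fractions
#'
#' Fills per-cluster summaries (size, mean Pearson r, mean distance
#' correlation from the trajectory statistics) for both fractions and
#' counts, for every (EV cluster, fc cluster) pair, the features shared
#' between them.
#'
#' @param clusters_EV,clusters_fc `ClusterResult` objects.
#' @param stats trajectory statistics data.frame (columns feature_id,
#'   fraction, pearson_r, dcor).
#' @return list with `summary_EV`, `summary_fc` (cluster, size,
#'   mean_pearson_r, mean_dcor; means `NA` when no stats overlap) and
#'   `overlap` (matrix, EV clusters x fc clusters, shared feature counts).
#' @export
summarize_and_map <- function(clusters_EV, clusters_fc, stats) {
  summarize_one <- function(cr, fr) {
    st <- stats[stats$fraction == fr, ]
    asg <- cr$assignments
    r <- st$pearson_r[match(asg$feature_id, st$feature_id)]
    d <- st$dcor[match(asg$feature_id, st$feature_id)]
    agg <- lapply(split(seq_len(nrow(asg)), asg$cluster), function(i) {
      c(size = length(i),
        mean_pearson_r = if (all(is.na(r[i]))) NA_real_ else
          mean(r[i], na.rm = TRUE),
        mean_dcor = if (all(is.na(d[i]))) NA_real_ else
          mean(d[i], na.rm = TRUE))
    })
    data.frame(cluster = as.integer(names(agg)),
               do.call(rbind, agg), row.names = NULL)
  }
  ev <- clusters_EV$assignments
  fc <- clusters_fc$assignments
  shared <- intersect(ev$feature_id, fc$feature_id)
  cl_ev <- ev$cluster[match(shared, ev$feature_id)]
  cl_fc <- fc$cluster[match(shared, fc$feature_id)]
  overlap <- table(factor(cl_ev, sort(unique(ev$cluster))),
                   factor(cl_fc, sort(unique(fc$cluster))))
  list(summary_EV = summarize_one(clusters_EV, "EV"),
       summary_fc = summarize_one(clusters_fc, "fc"),
       overlap = unclass(overlap))
}
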