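#' Read an expression matrix with its sample and feature sheets
#'
#' Reads the three tab-separated inputs of the pipeline and cross-validates
#' them: the count matrix (first column `feature_id`, remaining columns one
#' per sample), the sample sheet (`sample_id`, `mouse_id`, `age_months`,
#' `fraction`) and the feature sheet (`feature_id`, `rna_class`).
#'
#' @param matrix_path path to the count matrix TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @param feature_sheet_path path to the feature sheet TSV.
#' @param unit unit of the stored values; raw counts by default.
#' @return a list with elements `expr` (an [expression_matrix()]), `samples`
#'   (data.frame) and `features` (data.frame).
#' @export
read_expression <- function(matrix_path, sample_sheet_path, feature_sheet_path,
                            unit = "raw_counts") {
  for (p in c(matrix_path, sample_sheet_path, feature_sheet_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix TSV needs a feature_id column plus samples",
                           call. = FALSE)
  fid <- as.character(raw[[1L]])
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s) in matrix: ",
         paste(unique(fid[duplicated(fid)])[1:min(5, sum(duplicated(fid)))],
               collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- fid
  expr <- expression_matrix(values, unit)

  samples <- utils::read.delim(sample_sheet_path, sep = "\t",
                               stringsAsFactors = FALSE)
  features <- utils::read.delim(feature_sheet_path, sep = "\t",
                                stringsAsFactors = FALSE)
  validate_annotations(expr, samples, features)
  list(expr = expr, samples = samples, features = features)
}

#' Cross-validate expression matrix against its annotation sheets
#'
#' @param expr an `ExpressionMatrix`.
#' @param samples sample sheet data.frame with columns `sample_id`,
#'   `mouse_id`, `age_months`, `fraction`.
#' @param features feature sheet data.frame with columns `feature_id`,
#'   `rna_class`.
#' @return invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_annotations <- function(expr, samples, features) {
  need_s <- c("sample_id", "mouse_id", "age_months", "fraction")
  if (!all(need_s %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  need_f <- c("feature_id", "rna_class")
  if (!all(need_f %in% names(features))) {
    stop("feature sheet must have columns: ", paste(need_f, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id in feature sheet", call. = FALSE)
  }
  miss_s <- setdiff(expr$sample_ids, samples$sample_id)
  if (length(miss_s)) {
    stop("sample(s) in matrix absent from sample sheet: ",
         paste(utils::head(miss_s, 5), collapse = ", "), call. = FALSE)
  }
  miss_f <- setdiff(expr$feature_ids, features$feature_id)
  if (length(miss_f)) {
    stop("feature(s) in matrix absent from feature sheet: ",
         paste(utils::head(miss_f, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(samples$age_months)) || any(samples$age_months <= 0)) {
    stop("age_months must be positive", call. = FALSE)
  }
  if (!all(samples$fraction %in% c("EV", "fc"))) {
    stop("fraction must be 'EV' or 'fc'", call. = FALSE)
  }
  if (any(!nzchar(features$rna_class)) || anyNA(features$rna_class)) {
    stop("rna_class must be non-empty for every feature", call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalize raw counts to reads per million
#'
#' Scales every sample (column) so that its library sums to one million
#' reads. Library size is the column sum over all features present in the
#' matrix; normalization is done once, before any class subsetting.
#'
#' @param x an `ExpressionMatrix` with `unit == "raw_counts"`.
#' @return an `ExpressionMatrix` with `unit == "rpm"`, same dimensions and
#'   ordering.
#' @export
normalize_rpm <- function(x) {
  validate_expression_matrix(x)
  if (x$unit != "raw_counts") stop("input must be raw counts", call. = FALSE)
  libsize <- colSums(x$values)
  zero <- libsize <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(x$sample_ids[zero], collapse = ", "), call. = FALSE)
  }
  v <- sweep(x$values, 2L, libsize, "/") * 1e6
  expression_matrix(v, "rpm")
}

#' Filter to expressed features
#'
#' Keeps features with at least `min_rpm` reads per million in at least
#' `min_samples` samples (the study's expression filter is 5 RPM in at least
#' one sample; the threshold is inclusive).
#'
#' @param x an `ExpressionMatrix` in RPM units.
#' @param min_rpm expression threshold in RPM (default 5).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 1).
#' @return the filtered `ExpressionMatrix`; the sample set is unchanged.
#' @export
filter_expressed <- function(x, min_rpm = 5, min_samples = 1L) {
  validate_expression_matrix(x)
  if (x$unit != "rpm") stop("input must be RPM-normalized", call. = FALSE)
  keep <- rowSums(x$values >= min_rpm) >= min_samples
  expression_matrix(x$values[keep, , drop = FALSE], "rpm")
}

#' Per-class expression summaries
#'
#' Computes, per RNA class and plasma fraction: the total read share (the
#' class's proportion of all reads in that fraction), a detection curve (the
#' fraction of class members whose maximum RPM meets each threshold), and
#' the detected-feature overlap between the EV and fc fractions.
#'
#' @param x an `ExpressionMatrix` in RPM units.
#' @param feats feature sheet data.frame (`feature_id`, `rna_class`).
#' @param samples sample sheet data.frame.
#' @param thresholds numeric RPM thresholds for the detection curves.
#' @param min_rpm,min_samples detection rule used for the overlap counts,
#'   same semantics as [filter_expressed()].
#' @return a list with data.frames `read_share` (class, fraction, share),
#'   `detection` (class, fraction, threshold, detected_fraction) and
#'   `overlap` (class, ev_only, fc_only, both).
#' @export
class_summary <- function(x, feats, samples,
                          thresholds = c(0, 1, 5, 10, 50, 100),
                          min_rpm = 5, min_samples = 1L) {
  validate_expression_matrix(x)
  if (x$unit != "rpm") stop("input must be RPM-normalized", call. = FALSE)
  validate_annotations(x, samples, feats)
  cls <- feats$rna_class[match(x$feature_ids, feats$feature_id)]
  if (!length(unique(cls))) stop("empty class vocabulary", call. = FALSE)
  frs <- samples$fraction[match(x$sample_ids, samples$sample_id)]

  share <- detection <- list()
  det_sets <- list()
  for (fr in unique(frs)) {
    sub <- x$values[, frs == fr, drop = FALSE]
    tot <- sum(sub)
    cls_tot <- tapply(rowSums(sub), cls, sum)
    share[[fr]] <- data.frame(rna_class = names(cls_tot), fraction = fr,
                              share = as.numeric(cls_tot) / tot,
                              row.names = NULL)
    mx <- apply(sub, 1L, max)
    for (th in thresholds) {
      det <- tapply(mx >= th, cls, mean)
      detection[[paste(fr, th)]] <- data.frame(
        rna_class = names(det), fraction = fr, threshold = th,
        detected_fraction = as.numeric(det), row.names = NULL)
    }
    det_sets[[fr]] <- x$feature_ids[rowSums(sub >= min_rpm) >= min_samples]
  }
  overlap <- NULL
  if (all(c("EV", "fc") %in% names(det_sets))) {
    ov <- lapply(split(x$feature_ids, cls), function(ids) {
      ev <- ids %in% det_sets[["EV"]]
      fc <- ids %in% det_sets[["fc"]]
      c(ev_only = sum(ev & !fc), fc_only = sum(!ev & fc), both = sum(ev & fc))
    })
    overlap <- data.frame(rna_class = names(ov),
                          do.call(rbind, ov), row.names = NULL)
  }
  list(read_share = do.call(rbind, share),
       detection = do.call(rbind, detection),
       overlap = overlap)
}

#' Write an ExpressionMatrix as TSV
#'
#' Inverse of the matrix part of [read_expression()]: first column
#' `feature_id`, one column per sample, tab separated, no quoting.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(feature_id = x$feature_ids, x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
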