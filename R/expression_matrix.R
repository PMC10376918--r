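#' Expression matrix container
#'
#' A light S3 container for a non-negative feature-by-sample expression
#' matrix, the substrate of every stage of the pipeline. Rows are features
#' (small non-coding RNAs), columns are samples. The `unit` field records
#' whether entries are raw read counts or reads per million (RPM).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique rownames (feature ids) and colnames (sample ids).
#' @param unit `"raw_counts"` or `"rpm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `unit`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' x <- expression_matrix(m, "raw_counts")
#' dim(x)
#' @export
expression_matrix <- function(values, unit = c("raw_counts", "rpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)",
         call. = FALSE)
  }
  x <- structure(
    list(values = values,
         feature_ids = rownames(values),
         sample_ids = colnames(values),
         unit = unit),
    class = "ExpressionMatrix")
  validate_expression_matrix(x)
  x
}

#' Validate an ExpressionMatrix
#'
#' Checks the container invariants: numeric non-negative entries, unique
#' feature and sample ids, dimensions consistent with the id vectors.
#'
#' @param x an `ExpressionMatrix`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (anyNA(v) || any(!is.finite(v))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(x$feature_ids)) {
    dup <- unique(x$feature_ids[duplicated(x$feature_ids)])
    stop("duplicate feature id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_ids)) {
    dup <- unique(x$sample_ids[duplicated(x$sample_ids)])
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(v) != length(x$feature_ids) || ncol(v) != length(x$sample_ids)) {
    stop("dimension mismatch between values and id vectors", call. = FALSE)
  }
  if (!x$unit %in% c("raw_counts", "rpm")) {
    stop("unit must be 'raw_counts' or 'rpm'", call. = FALSE)
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Subset an ExpressionMatrix
#'
#' @param x an `ExpressionMatrix`.
#' @param i feature index (integer, logical or character).
#' @param j sample index.
#' @param ... ignored.
#' @return the subsetted `ExpressionMatrix` (dimensions always kept).
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  expression_matrix(v[i, j, drop = FALSE], x$unit)
}
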