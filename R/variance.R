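#' Principal-variance-component attribution of expression variance
#'
#' PVCA-style decomposition: principal components of the standardized
#' sample-by-feature matrix are retained until their cumulative explained
#' variance reaches `pc_variance_threshold`; on each retained component a
#' one-way random-effects variance component is estimated for every factor
#' by method of moments (negative estimates truncated at 0), with the
#' residual taken as the pooled within-cell variance of the full factor
#' cross (falling back to the smallest within-factor mean square when the
#' cross leaves no residual degrees of freedom). Component attributions are
#' averaged with eigenvalue weights and normalized to sum to 1.
#'
#' @param x an `ExpressionMatrix`.
#' @param samples sample sheet data.frame.
#' @param factors column names of `samples` to attribute variance to
#'   (default age_months, fraction, mouse_id).
#' @param pc_variance_threshold cumulative variance cut-off for PC
#'   retention (default 0.6).
#' @return list of class `VarianceAttribution`: `proportions` (named,
#'   factors plus `residual`, non-negative, summing to 1), `n_components`,
#'   `eigenvalues`.
#' @export
variance_attribution <- function(x, samples,
                                 factors = c("age_months", "fraction",
                                             "mouse_id"),
                                 pc_variance_threshold = 0.6) {
  validate_expression_matrix(x)
  meta <- samples[match(x$sample_ids, samples$sample_id), , drop = FALSE]
  fac <- lapply(factors, function(f) factor(meta[[f]]))
  names(fac) <- factors
  for (f in factors) {
    if (nlevels(fac[[f]]) < 2) stop("factor has < 2 levels: ", f, call. = FALSE)
  }
  # 1:1 confounded factors carry identical groupings and cannot be separated
  if (length(factors) > 1) {
    for (i in seq_along(factors)[-1]) for (j in seq_len(i - 1)) {
      gi <- as.integer(fac[[i]]); gj <- as.integer(fac[[j]])
      if (nlevels(fac[[i]]) == nlevels(fac[[j]]) &&
          all(tapply(gj, gi, function(v) length(unique(v))) == 1L)) {
        stop("factors confounded 1:1: ", factors[j], " and ", factors[i],
             call. = FALSE)
      }
    }
  }
  v <- x$values
  sds <- apply(v, 1L, stats::sd)
  z <- zscore_rows(v[sds > 0, , drop = FALSE])
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  n_keep <- which(cumsum(prop) >= pc_variance_threshold)[1]
  if (is.na(n_keep)) n_keep <- length(ev)
  n_keep <- max(n_keep, 1L)

  cell <- interaction(as.data.frame(fac), drop = TRUE)
  per_pc <- vapply(seq_len(n_keep), function(i) {
    y <- pc$x[, i]
    comp <- vapply(fac, function(g) mom_variance_component(y, g), numeric(1))
    res <- within_cell_variance(y, cell)
    if (is.na(res)) {
      res <- min(vapply(fac, function(g) pooled_within_ms(y, g), numeric(1)))
    }
    out <- c(comp, residual = res)
    out / sum(out)
  }, numeric(length(fac) + 1L))
  w <- ev[seq_len(n_keep)] / sum(ev[seq_len(n_keep)])
  props <- as.numeric(per_pc %*% w)
  names(props) <- c(factors, "residual")
  props <- props / sum(props)
  structure(list(proportions = props, n_components = n_keep,
                 eigenvalues = ev[seq_len(n_keep)]),
            class = "VarianceAttribution")
}

# one-way random-effects method-of-moments variance component:
# (MSB - MSW) / n0 with the unbalanced-design n0, truncated at 0
mom_variance_component <- function(y, g) {
  g <- droplevels(g)
  ni <- tabulate(g)
  a <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean)
  msb <- sum(ni * (gm - mean(y))^2) / (a - 1)
  msw <- pooled_within_ms(y, g)
  n0 <- (n - sum(ni^2) / n) / (a - 1)
  max((msb - msw) / n0, 0)
}

pooled_within_ms <- function(y, g) {
  g <- droplevels(g)
  ni <- tabulate(g)
  if (all(ni <= 1)) return(stats::var(y))
  sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (length(y) - nlevels(g))
}

# residual = pooled within-cell variance of the full factor cross;
# NA when every cell has a single sample (no residual df)
within_cell_variance <- function(y, cell) {
  cell <- droplevels(cell)
  ni <- tabulate(cell)
  if (all(ni <= 1)) return(NA_real_)
  sum(tapply(y, cell, function(v) sum((v - mean(v))^2))) /
    (length(y) - nlevels(cell))
}
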