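#' Pearson age correlation of one feature
#'
#' Product-moment correlation of a feature's expression with sample age.
#' A zero-variance feature has no defined correlation and returns `NA`
#' (excluded downstream rather than set to 0).
#'
#' @param values numeric expression vector.
#' @param ages ages in months, same length.
#' @return Pearson r in \[-1, 1\], or `NA_real_` if the feature variance is 0.
#' @export
age_correlation <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch", call. = FALSE)
  if (length(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(ages) == 0) stop("ages must not all be equal", call. = FALSE)
  if (stats::sd(values) == 0) return(NA_real_)
  stats::cor(values, ages)
}

#' Sample distance correlation
#'
#' Dependence measure in \[0, 1\] computed from double-centred pairwise
#' Euclidean distance matrices: dCor = dCov / sqrt(dVar_x dVar_y), with the
#' convention dCor = 0 when either distance variance is 0 (e.g. a constant
#' argument). Unlike Pearson's r it detects nonlinear association.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  A <- dc_center(abs(outer(x, x, "-")))
  B <- dc_center(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  r2 <- dcov2 / sqrt(dvarx * dvary)
  sqrt(max(r2, 0))
}

dc_center <- function(d) {
  d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
}

#' Per-feature trajectory statistics
#'
#' Computes Pearson and distance correlation with age for every feature of
#' an expression matrix, per fraction.
#'
#' @param x an `ExpressionMatrix` (RPM recommended).
#' @param samples sample sheet data.frame.
#' @return data.frame with columns feature_id, fraction, pearson_r, dcor
#'   (Pearson `NA` for zero-variance features; dcor 0 by convention).
#' @export
trajectory_stats <- function(x, samples) {
  validate_expression_matrix(x)
  ages_all <- samples$age_months[match(x$sample_ids, samples$sample_id)]
  frac_all <- samples$fraction[match(x$sample_ids, samples$sample_id)]
  out <- lapply(unique(frac_all), function(fr) {
    v <- x$values[, frac_all == fr, drop = FALSE]
    ages <- ages_all[frac_all == fr]
    data.frame(
      feature_id = x$feature_ids,
      fraction = fr,
      pearson_r = apply(v, 1L, age_correlation, ages = ages),
      dcor = apply(v, 1L, distance_correlation, y = ages),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify features as linear or predominantly nonlinear
#'
#' Fits a cubic smoothing spline of the distance correlation on the Pearson
#' correlation across features (stats::smooth.spline at the given
#' equivalent degrees of freedom) and flags features whose dcor lies at
#' least `threshold` away from the spline (in either direction) as
#' predominantly nonlinear: `nonlinear_positive` when their Pearson r > 0,
#' `nonlinear_negative` otherwise. All other features are `linear`.
#'
#' @param stats data.frame with columns `pearson_r` and `dcor` (one
#'   fraction at a time); rows with `NA` Pearson are left uncategorized.
#' @param df equivalent degrees of freedom of the spline (default 7).
#' @param threshold absolute residual cut-off (default 0.15).
#' @return `stats` with columns `spline_fit`, `residual`, `category` added.
#' @export
classify_nonlinear <- function(stats, df = 7, threshold = 0.15) {
  ok <- is.finite(stats$pearson_r) & is.finite(stats$dcor)
  if (sum(ok) < df + 2) {
    stop("need at least df + 2 features with defined statistics", call. = FALSE)
  }
  fit <- stats::smooth.spline(stats$pearson_r[ok], stats$dcor[ok], df = df)
  pred <- stats::predict(fit, stats$pearson_r[ok])$y
  stats$spline_fit <- NA_real_
  stats$residual <- NA_real_
  stats$spline_fit[ok] <- pred
  stats$residual[ok] <- stats$dcor[ok] - pred
  stats$category <- NA_character_
  flagged <- ok & abs(stats$residual) >= threshold
  stats$category[ok] <- "linear"
  stats$category[flagged & stats$pearson_r > 0] <- "nonlinear_positive"
  stats$category[flagged & stats$pearson_r <= 0] <- "nonlinear_negative"
  stats
}

#' Cross-fraction sign-quadrant concordance
#'
#' Classifies each feature by the sign pair of its age correlation in the
#' EV and fc fractions and tests the four quadrant counts against the
#' uniform 25 percent null expected under independent random signs.
#' Features with a zero or undefined correlation in either fraction are
#' excluded and counted in `n_excluded`. A chi-square goodness-of-fit test
#' is used, replaced by an exact multinomial computation when any expected
#' count falls below 5.
#'
#' @param r_EV,r_fc matched per-feature correlation vectors.
#' @return list of class `QuadrantTable`: `counts` and `fractions` (named
#'   `EV+/fc+`, `EV+/fc-`, `EV-/fc+`, `EV-/fc-`), `n_excluded`,
#'   `chisq_stat`, `p_value`, `method`.
#' @export
quadrant_concordance <- function(r_EV, r_fc) {
  if (length(r_EV) != length(r_fc)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(r_EV) & is.finite(r_fc) & r_EV != 0 & r_fc != 0
  n_excluded <- length(r_EV) - sum(ok)
  if (!sum(ok)) stop("no features with defined signs in both fractions",
                     call. = FALSE)
  ev <- r_EV[ok] > 0
  fc <- r_fc[ok] > 0
  counts <- c(`EV+/fc+` = sum(ev & fc), `EV+/fc-` = sum(ev & !fc),
              `EV-/fc+` = sum(!ev & fc), `EV-/fc-` = sum(!ev & !fc))
  n <- sum(counts)
  expected <- n / 4
  stat <- sum((counts - expected)^2 / expected)
  if (expected < 5) {
    p <- exact_multinomial_p(counts)
    method <- "exact multinomial"
  } else {
    p <- stats::pchisq(stat, df = 3, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(counts = counts, fractions = counts / n,
                 n_excluded = n_excluded, chisq_stat = stat,
                 p_value = p, method = method),
            class = "QuadrantTable")
}

# Exact multinomial goodness-of-fit p against equal cell probabilities:
# total probability of outcomes at least as extreme (by chi-square
# distance) as observed. Enumerates all compositions of n into 4 cells, so
# only used at the small n where the chi-square approximation fails.
exact_multinomial_p <- function(counts, prob = rep(1 / 4, 4)) {
  n <- sum(counts)
  expected <- n * prob
  stat_obs <- sum((counts - expected)^2 / expected)
  p <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    x <- c(a, b, cc, d)
    if (sum((x - expected)^2 / expected) >= stat_obs - 1e-12) {
      p <- p + stats::dmultinom(x, prob = prob)
    }
  }
  min(p, 1)
}

#' Permutation test for a cross-fraction mean correlation shift
#'
#' Observed statistic: the mean per-feature Pearson age correlation within
#' each fraction and their difference (EV minus fc). The null distribution
#' is built by shuffling the age labels across samples within each fraction
#' and recomputing the difference; feature values stay fixed, preserving
#' the correlation structure among features while breaking the age signal.
#' Two-sided p with add-one correction, p = (b + 1) / (B + 1).
#'
#' @param matrix_EV,matrix_fc `ExpressionMatrix` objects sharing a feature
#'   set (>= 3 samples each).
#' @param ages_EV,ages_fc ages in months per sample of each matrix.
#' @param n_permutations number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class `MeanShiftResult`: observed means per fraction,
#'   `observed_difference`, `null_means` (null differences), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mean_shift_permutation_test <- function(matrix_EV, matrix_fc, ages_EV, ages_fc,
                                        n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!identical(matrix_EV$feature_ids, matrix_fc$feature_ids)) {
    stop("matrices must share the same feature set", call. = FALSE)
  }
  if (ncol(matrix_EV$values) < 3 || ncol(matrix_fc$values) < 3) {
    stop("need at least 3 samples per fraction", call. = FALSE)
  }
  mean_r <- function(v, ages) {
    r <- suppressWarnings(stats::cor(t(v), ages))
    mean(r[is.finite(r)])
  }
  obs_ev <- mean_r(matrix_EV$values, ages_EV)
  obs_fc <- mean_r(matrix_fc$values, ages_fc)
  obs <- obs_ev - obs_fc
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    mean_r(matrix_EV$values, sample(ages_EV)) -
      mean_r(matrix_fc$values, sample(ages_fc))
  }, numeric(1))
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_permutations + 1)
  structure(list(observed_mean_EV = obs_ev, observed_mean_fc = obs_fc,
                 observed_difference = obs, null_means = null,
                 p_value = p, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "MeanShiftResult")
}

#' Class-level expression relative to the youngest age
#'
#' Per RNA class, fraction and age: mean total class RPM divided by its
#' value at the baseline age, log2-transformed. The baseline column is
#' exactly 0; classes with zero baseline expression are flagged `NA`
#' rather than infinite.
#'
#' @param x an `ExpressionMatrix` in RPM units.
#' @param samples sample sheet data.frame.
#' @param feats feature sheet data.frame.
#' @param baseline_age baseline in months (default 2).
#' @return data.frame with columns rna_class, fraction, age_months,
#'   log2_ratio.
#' @export
baseline_relative_expression <- function(x, samples, feats, baseline_age = 2) {
  validate_expression_matrix(x)
  if (x$unit != "rpm") stop("input must be RPM-normalized", call. = FALSE)
  ages <- samples$age_months[match(x$sample_ids, samples$sample_id)]
  frac <- samples$fraction[match(x$sample_ids, samples$sample_id)]
  if (!baseline_age %in% ages) stop("baseline age absent from cohort",
                                    call. = FALSE)
  cls <- feats$rna_class[match(x$feature_ids, feats$feature_id)]
  out <- list()
  for (fr in unique(frac)) {
    for (cl in unique(cls)) {
      v <- x$values[cls == cl, frac == fr, drop = FALSE]
      a <- ages[frac == fr]
      m <- tapply(colSums(v), a, mean)     # mean total class RPM per age
      base <- m[as.character(baseline_age)]
      ratio <- if (is.na(base) || base == 0) rep(NA_real_, length(m)) else
        log2(as.numeric(m) / as.numeric(base))
      out[[paste(fr, cl)]] <- data.frame(
        rna_class = cl, fraction = fr,
        age_months = as.numeric(names(m)), log2_ratio = ratio,
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
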