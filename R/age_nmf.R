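#' Rescale a non-negative matrix by its maximum
#'
#' Divides every element by the global maximum, mapping the matrix into
#' \[0, 1\] with at least one entry exactly 1.
#'
#' @param x non-negative numeric matrix with a positive maximum.
#' @return the rescaled matrix.
#' @export
normalize_max <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix",
                                            call. = FALSE)
  if (any(x < 0)) stop("matrix must be non-negative", call. = FALSE)
  mx <- max(x)
  if (mx <= 0) stop("all-zero matrix cannot be rescaled", call. = FALSE)
  x / mx
}

# Euclidean projection of a vector onto the probability simplex
# (Held-Wolfe-Crowder / Duchi et al. sort-based algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Constrained non-negative matrix factorization age classifier
#'
#' Decomposes a matrix `D` (features x samples, rescaled to \[0, 1\]) as
#' `D ~ T P`, minimizing the squared Frobenius norm subject to
#' `0 <= T <= 1`, `0 <= P <= 1`, and every column of `P` summing to 1, so
#' that column j of `P` holds the membership probabilities of sample j over
#' the `k` age groups. Solved by alternating projected least squares:
#' T-step = row-wise least squares clipped to \[0, 1\]; P-step = column-wise
#' least squares followed by Euclidean projection onto the probability
#' simplex. A sweep is only accepted if it does not increase the objective,
#' so the returned objective never exceeds that of its own initialization.
#' The best of `n_restarts` seeded random restarts is returned.
#'
#' @param D matrix with entries in \[0, 1\] (use [normalize_max()] first).
#' @param k number of age groups (default 3; must be >= 2).
#' @param n_restarts random restarts (default 10).
#' @param max_iter maximum sweeps per restart (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param seed RNG seed.
#' @return list of class `AgeFactorization`: `T` (m x k), `P` (k x n),
#'   `k`, `objective`, `labels` (argmax group per sample, ties to the
#'   lowest index), `n_restarts`, `n_iterations`, `seed`.
#' @export
fit_age_nmf <- function(D, k = 3L, n_restarts = 10L, max_iter = 500L,
                        tol = 1e-6, seed = 1L) {
  if (!is.matrix(D) || any(!is.finite(D))) {
    stop("D must be a finite numeric matrix", call. = FALSE)
  }
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  m <- nrow(D); n <- ncol(D)
  if (m < k || n < k) stop("matrix too small for k groups", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    Tm <- matrix(stats::runif(m * k), m, k)
    P <- matrix(stats::rexp(k * n), k, n)          # flat Dirichlet columns
    P <- sweep(P, 2L, colSums(P), "/")
    obj <- sum((D - Tm %*% P)^2)
    iters <- 0L
    for (it in seq_len(max_iter)) {
      # T-step: rows of T solve min ||D - T P||; clip to the unit box
      PPt <- P %*% t(P)
      Tnew <- t(solve(PPt + diag(1e-10, k), P %*% t(D)))
      Tnew <- pmin(pmax(Tnew, 0), 1)
      # P-step: columns solve least squares, then simplex projection
      TtT <- crossprod(Tnew)
      Pls <- solve(TtT + diag(1e-10, k), crossprod(Tnew, D))
      Pnew <- apply(Pls, 2L, project_simplex)
      obj_new <- sum((D - Tnew %*% Pnew)^2)
      if (obj_new > obj) break                     # non-descent: stop sweep
      iters <- it
      conv <- (obj - obj_new) <= tol * max(obj, .Machine$double.eps)
      Tm <- Tnew; P <- Pnew; obj <- obj_new
      if (conv) break
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(T = Tm, P = P, k = as.integer(k), objective = obj,
                   n_iterations = iters, restart = r)
    }
  }
  labels <- max.col(t(best$P), ties.method = "first")
  structure(c(best, list(labels = labels, n_restarts = as.integer(n_restarts),
                         seed = as.integer(seed))),
            class = "AgeFactorization")
}

# all permutations of 1..k (k small: k! enumerations)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Label samples and score against ground truth
#'
#' Predicted group of each sample = argmax over the k membership
#' probabilities of its `P` column (ties broken to the lowest index). The
#' rows of `P` are invariant to permutation, so the accuracy is maximized
#' over all k! bijections from predicted indices to the truth labels.
#'
#' @param f an `AgeFactorization`.
#' @param truth character vector of true group labels per sample, drawn
#'   from `group_levels`.
#' @param group_levels ordered label set (default young/middle/old).
#' @return list with `labels` (predicted indices), `mapped_labels`
#'   (predicted group names under the best permutation), `accuracy`,
#'   `permutation_used` (index -> group name), `confusion` (table).
#' @export
classify_and_score <- function(f, truth,
                               group_levels = c("young", "middle", "old")) {
  stopifnot(inherits(f, "AgeFactorization"))
  if (length(truth) != ncol(f$P)) stop("truth length must equal n samples",
                                       call. = FALSE)
  if (!all(truth %in% group_levels)) {
    stop("truth contains unknown label(s): ",
         paste(setdiff(truth, group_levels), collapse = ", "), call. = FALSE)
  }
  k <- f$k
  if (length(group_levels) != k) {
    stop("group_levels must have length k", call. = FALSE)
  }
  labels <- max.col(t(f$P), ties.method = "first")
  perms <- permutations_of(k)
  acc <- apply(perms, 1L, function(p) {
    mean(group_levels[p][labels] == truth)
  })
  best <- which.max(acc)
  mapping <- stats::setNames(group_levels[perms[best, ]], seq_len(k))
  mapped <- group_levels[perms[best, ]][labels]
  list(labels = labels, mapped_labels = mapped, accuracy = max(acc),
       permutation_used = mapping,
       confusion = table(truth = factor(truth, group_levels),
                         predicted = factor(mapped, group_levels)))
}
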