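# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: explicit loops, textbook formulas, tiny
# brute-force algorithms.

# brute-force distance correlation: explicit O(n^2) double centring
bf_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j]); b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- 0; dvx <- 0; dvy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    dvx <- dvx + A[i, j]^2
    dvy <- dvy + B[i, j]^2
  }
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt((dcov2 / n^2) / sqrt((dvx / n^2) * (dvy / n^2)))
}

# textbook chi-square goodness-of-fit against equal probabilities
bf_chisq_gof <- function(counts) {
  e <- sum(counts) / length(counts)
  stat <- sum((counts - e)^2 / e)
  list(stat = stat,
       p = stats::pchisq(stat, df = length(counts) - 1, lower.tail = FALSE))
}

# naive complete-linkage agglomeration over a distance matrix; returns the
# flat partition from cutting at height h (merges with height <= h applied)
bf_complete_linkage_cut <- function(d, h) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  groups <- as.list(seq_len(n))
  repeat {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      link <- max(dm[groups[[i]], groups[[j]]])
      if (link < best) { best <- link; bi <- i; bj <- j }
    }
    if (!is.finite(best) || best > h) break
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
    if (length(groups) == 1) break
  }
  out <- integer(n)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# partitions equal up to label renaming: one-to-one block correspondence
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
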