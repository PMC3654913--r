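# Independent oracles used across tests.  Deliberately written with plain
# loops / outer products, never calling the package's own closed-form or
# vectorized code paths.

# tau-b by O(n^2) pair enumeration: expand the confusion matrix to
# per-sample (truth, prediction) vectors and count concordant, discordant
# and tied pairs directly.
oracle_tau_b <- function(x) {
  x <- as.matrix(x)
  tt <- integer(0)
  pp <- integer(0)
  for (j in seq_len(nrow(x))) {
    for (k in seq_len(ncol(x))) {
      tt <- c(tt, rep(j, x[j, k]))
      pp <- c(pp, rep(k, x[j, k]))
    }
  }
  n <- length(tt)
  if (n < 2) return(NA_real_)
  st <- sign(outer(tt, tt, "-"))
  sp <- sign(outer(pp, pp, "-"))
  num <- sum(st * sp) / 2
  den <- sqrt((sum(st != 0) / 2) * (sum(sp != 0) / 2))
  if (den == 0) NA_real_ else num / den
}

# brute-force cell assignment: for each cell, scan classes one by one and
# keep the largest class index attaining the maximal n_ij / n_+j ratio
# (classes with zero total skipped); empty cells are NA.
oracle_assign <- function(counts_mat, class_totals) {
  ncell <- nrow(counts_mat)
  J <- ncol(counts_mat)
  out <- rep(NA_integer_, ncell)
  ties <- integer(0)
  for (i in seq_len(ncell)) {
    if (sum(counts_mat[i, ]) == 0) next
    best_j <- NA_integer_
    best_r <- -Inf
    tied <- FALSE
    for (j in seq_len(J)) {
      if (class_totals[j] == 0) next
      r <- counts_mat[i, j] / class_totals[j]
      if (r > best_r) {
        best_r <- r
        best_j <- j
        tied <- FALSE
      } else if (r == best_r) {
        best_j <- j  # largest index among ties
        tied <- TRUE
      }
    }
    out[i] <- best_j
    if (tied) ties <- c(ties, i)
  }
  list(assignment = out, tie_cells = ties)
}

# random confusion matrix with n total observations spread over J x J cells
random_confusion <- function(J, n) {
  cells <- sample.int(J * J, n, replace = TRUE,
                      prob = stats::runif(J * J))
  matrix(tabulate(cells, nbins = J * J), J, J)
}

# small random dataset generator for property tests
random_dataset <- function(n, p, J, miss_rate = 0) {
  g <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (miss_rate > 0)
    g[stats::runif(n * p) < miss_rate] <- NA_integer_
  y <- sample.int(J, n, replace = TRUE)
  # guarantee every class present so J is inferred consistently
  y[seq_len(J)] <- seq_len(J)
  omdr_dataset(g, y, n_classes = J)
}
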