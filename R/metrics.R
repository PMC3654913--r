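#' Kendall's tau-b from a confusion matrix
#'
#' The evaluation measure for ordinal classifiers: rank concordance between
#' true and predicted classes, corrected for ties,
#' \deqn{\tau_b = (P - Q) / \sqrt{(N_0 - T_r)(N_0 - T_c)}}
#' with P/Q the concordant/discordant pair counts over the `J x J` table,
#' `N0 = n(n-1)/2`, and `T_r`, `T_c` the tied-pair counts from row and
#' column totals.  Computed in closed form from cell products — exact and
#' O(J^4) per table — rather than by expanding to per-sample vectors.
#'
#' Unclassified samples (`n_excluded`) carry no ordinal information and are
#' omitted; `n_effective` records how many samples were scored.  A
#' degenerate table (all mass in one row or one column, or fewer than two
#' samples) has no defined tau-b and returns `NA`; in rankings an undefined
#' value sorts below any defined one.
#'
#' @param cm an `omdr_confusion` object, or a plain `J x J` count matrix.
#' @return tau-b in `[-1, 1]`, or `NA` when undefined; the number of scored
#'   samples is attached as attribute `n_effective`.
#' @examples
#' tau_b(matrix(c(10, 0, 0, 10), 2))   # perfect concordance: 1
#' tau_b(matrix(c(0, 10, 10, 0), 2))   # perfect discordance: -1
#' @export
tau_b <- function(cm) {
  x <- if (inherits(cm, "omdr_confusion")) cm$x else as.matrix(cm)
  v <- tau_b_array(array(x, dim = c(nrow(x), ncol(x), 1)))
  structure(v[1], n_effective = sum(x))
}

# Vectorized closed-form tau-b over an array of J x J tables (dim J,J,C).
# Used by the cross-validation scan so one call scores a whole chunk of
# candidate combinations.
tau_b_array <- function(X) {
  J <- dim(X)[1]
  K <- dim(X)[2]
  C <- dim(X)[3]
  n <- apply(X, 3, sum)
  P <- numeric(C)
  Q <- numeric(C)
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      xjk <- X[j, k, ]
      if (j < J && k < K)
        P <- P + xjk * colSums(matrix(X[(j + 1):J, (k + 1):K, , drop = FALSE],
                                      ncol = C))
      if (j < J && k > 1)
        Q <- Q + xjk * colSums(matrix(X[(j + 1):J, 1:(k - 1), , drop = FALSE],
                                      ncol = C))
    }
  }
  rs <- apply(X, c(1, 3), sum)  # J x C row totals
  cs <- apply(X, c(2, 3), sum)  # K x C col totals
  N0 <- n * (n - 1) / 2
  Tr <- colSums(rs * (rs - 1)) / 2
  Tc <- colSums(cs * (cs - 1)) / 2
  den <- sqrt((N0 - Tr) * (N0 - Tc))
  out <- rep(NA_real_, C)
  ok <- n >= 2 & den > 0
  out[ok] <- (P[ok] - Q[ok]) / den[ok]
  out
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean per-class recall, the conventional binary-MDR evaluation baseline.
#' For `J = 2` this is (sensitivity + specificity) / 2; for larger J it is
#' macro-averaged recall.  Classes with no true members are skipped from
#' the mean with a warning.
#'
#' @inheritParams tau_b
#' @return value in `[0, 1]`, `NA` if every class is empty; attribute
#'   `n_effective` as in [tau_b()].
#' @export
balanced_accuracy <- function(cm) {
  x <- if (inherits(cm, "omdr_confusion")) cm$x else as.matrix(cm)
  rs <- rowSums(x)
  if (all(rs == 0)) return(structure(NA_real_, n_effective = 0))
  if (any(rs == 0))
    warning("classes with no true members skipped from balanced accuracy")
  recall <- diag(x)[rs > 0] / rs[rs > 0]
  structure(mean(recall), n_effective = sum(x))
}
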