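# A separately coded classic binary MDR, used as the J = 2 reduction
# comparator.  Cells are labelled high risk (class 2) when the case:control
# ratio in the cell reaches the overall case:control ratio of the training
# data (ties -> high risk, the binary-MDR convention); CVC is the number of
# folds in which a combination is the single best classifier by training
# metric.  Independent of the package's classifier internals.

binary_mdr_fit <- function(genotypes, status, snp_indices) {
  m <- length(snp_indices)
  ncell <- 3L^m
  idx <- rep(1L, nrow(genotypes))
  for (k in seq_len(m))
    idx <- idx + genotypes[, snp_indices[k]] * 3L^(k - 1L)
  n_case <- sum(status == 2)
  n_ctrl <- sum(status == 1)
  lab <- rep(NA_integer_, ncell)
  for (i in seq_len(ncell)) {
    in_cell <- which(idx == i & !is.na(idx))
    if (!length(in_cell)) next
    cc <- sum(status[in_cell] == 2)
    ct <- sum(status[in_cell] == 1)
    # high risk iff cases/controls >= n_case/n_ctrl, i.e. cc*n_ctrl >= ct*n_case
    lab[i] <- if (cc * n_ctrl >= ct * n_case) 2L else 1L
  }
  lab
}

binary_mdr_predict <- function(lab, genotypes, snp_indices) {
  m <- length(snp_indices)
  idx <- rep(1L, nrow(genotypes))
  for (k in seq_len(m))
    idx <- idx + genotypes[, snp_indices[k]] * 3L^(k - 1L)
  out <- rep(NA_integer_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- lab[idx[ok]]
  out
}

# CVC with K = 1 over a fold plan: per fold, rank combinations by training
# tau-b (computed here through the pair-enumeration oracle), break ties by
# the first (lexicographically smallest) combination.
binary_mdr_cvc <- function(ds, combos, fold_assignments) {
  L <- max(fold_assignments)
  C <- ncol(combos)
  wins <- integer(C)
  for (l in seq_len(L)) {
    tr <- fold_assignments != l
    g <- ds$genotypes[tr, , drop = FALSE]
    y <- ds$phenotype[tr]
    taus <- numeric(C)
    for (ci in seq_len(C)) {
      lab <- binary_mdr_fit(g, y, combos[, ci])
      pred <- binary_mdr_predict(lab, g, combos[, ci])
      cm <- matrix(0L, 2, 2)
      for (s in seq_along(y)) {
        if (!is.na(pred[s])) cm[y[s], pred[s]] <- cm[y[s], pred[s]] + 1L
      }
      taus[ci] <- oracle_tau_b(cm)
    }
    taus[is.na(taus)] <- -Inf
    wins[which.max(taus)] <- wins[which.max(taus)] + 1L
  }
  wins
}
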