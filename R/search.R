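#' Enumerate all m-way SNP combinations
#'
#' All `choose(p, m)` sorted combinations of `m` SNPs out of `p`, in
#' lexicographic order, one combination per column.  The scan engine
#' consumes the matrix in chunks, so even order-3/4 candidate sets are
#' processed with bounded memory.
#'
#' @param p number of SNPs.
#' @param m interaction order, `1 <= m <= p`.
#' @return integer matrix `m x choose(p, m)`.
#' @examples
#' ncol(enumerate_exhaustive(50, 2))  # 1225
#' @export
enumerate_exhaustive <- function(p, m) {
  p <- as.integer(p)
  m <- as.integer(m)
  if (m < 1L || m > p) stop("need 1 <= m <= p")
  matrix(utils::combn(p, m), nrow = m)
}

#' Staged candidate enumeration from lower-order results
#'
#' The staged search used for large SNP panels: take the top `carry_k`
#' combinations at order m-1 (ranked by GCVC, then mean test metric, then
#' lexicographic order), pool the SNPs they contain, and emit every
#' m-subset of that pool.  With `carry_k = Inf` this saturates to the
#' exhaustive scan over all SNPs seen at the previous order.
#'
#' @param prev_scan an `omdr_scan` at order m-1, after [topk_select()].
#' @param carry_k number of top combinations whose SNPs are carried
#'   forward.
#' @param m target order.
#' @return integer matrix `m x n_candidates` (0 columns, with a warning,
#'   when the pool is smaller than m).
#' @export
staged_candidates <- function(prev_scan, carry_k, m) {
  if (is.null(prev_scan$gcvc)) stop("run topk_select() on the previous order first")
  tab <- scan_table(prev_scan)
  ord <- order(-tab$gcvc, -ifelse(is.na(tab$mean_test), -Inf, tab$mean_test),
               seq_len(nrow(tab)))
  keep <- ord[seq_len(min(carry_k, length(ord)))]
  pool <- sort(unique(as.vector(prev_scan$combos[, keep, drop = FALSE])))
  if (length(pool) < m) {
    warning("SNP pool smaller than target order; no candidates")
    return(matrix(integer(0), nrow = m))
  }
  matrix(pool[utils::combn(length(pool), m)], nrow = m)
}
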