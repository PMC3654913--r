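#' Empirical power study over simulated replicates
#'
#' Runs the full scan-and-select pipeline on replicate datasets simulated
#' from a genetic model with a declared causal SNP combination, and
#' summarizes, per interaction order, the four headline measures of the
#' simulation design:
#' \itemize{
#'   \item `power` (EP): proportion of replicates in which the causal
#'     combination is the top-ranked classifier at its own order;
#'   \item `mean_gcvc`: average GCVC of the per-order best classifier,
#'     scaled to `[0, 1]` by the number of folds;
#'   \item `trtb` / `tstb`: average training / testing metric of the
#'     per-order best classifier across replicates.
#' }
#' An `overall` row reports how often the causal pair wins the
#' across-order selection of [select_best_over_orders()].
#'
#' @param model an `omdr_model` whose causal SNPs will occupy
#'   `causal_positions`.
#' @param n_replicates replicate datasets (the full design uses 100).
#' @param orders interaction orders to scan (default `1:3`).
#' @param n,p samples and SNPs per replicate (defaults 1000 and 50).
#' @param causal_positions where the causal SNPs sit among the p columns.
#' @param L folds; `K` top-K selection size; `metric` evaluation measure.
#' @param K top-K selection size.
#' @param metric `"tau_b"` (default) or `"balanced_accuracy"`.
#' @param seed master seed (fold seeds and replicate seeds derive from it).
#' @param noncausal_maf MAF of non-causal SNPs.
#' @param keep_gcvc_by_combo also return, for the order matching the
#'   causal combination, the per-combination mean GCVC across replicates.
#' @return an `omdr_power` object: `summary` data.frame (one row per order
#'   plus `overall`), and optionally `gcvc_by_combo`.
#' @export
omdr_power <- function(model, n_replicates = 20, orders = 1:3, n = 1000,
                       p = 50, causal_positions = seq_along(model$mafs),
                       L = 10, K = 1, metric = "tau_b", seed = 1,
                       noncausal_maf = 0.3, keep_gcvc_by_combo = FALSE) {
  stopifnot(inherits(model, "omdr_model"))
  causal <- sort(as.integer(causal_positions))
  m_causal <- length(causal)
  combos_by_order <- lapply(orders, function(m) enumerate_exhaustive(p, m))
  names(combos_by_order) <- as.character(orders)
  hits <- setNames(numeric(length(orders)), as.character(orders))
  gsum <- tssum <- trsum <- hits
  overall_hits <- 0
  gcvc_combo_sum <- NULL
  causal_order_chr <- as.character(m_causal)
  for (r in seq_len(n_replicates)) {
    rseed <- child_seed(seed, r)
    ds <- simulate_dataset(model, n = n, p = p, causal_positions = causal,
                           noncausal_maf = noncausal_maf, seed = rseed)
    folds <- make_folds(ds, L = L, seed = child_seed(rseed, 1))
    scans <- lapply(combos_by_order, function(cm)
      topk_select(scan_combinations(ds, cm, folds, metric = metric), K = K))
    for (o in seq_along(orders)) {
      s <- scans[[o]]
      tab <- scan_table(s)
      ord <- order(-tab$gcvc, -ifelse(is.na(tab$mean_test), -Inf,
                                      tab$mean_test), seq_len(nrow(tab)))
      top <- tab[ord[1], ]
      oc <- as.character(orders[o])
      if (orders[o] == m_causal &&
          all(s$combos[, top$combo_index] == causal))
        hits[oc] <- hits[oc] + 1
      gsum[oc] <- gsum[oc] + top$gcvc / L
      trsum[oc] <- trsum[oc] + top$mean_train
      tssum[oc] <- tssum[oc] + top$mean_test
      if (keep_gcvc_by_combo && oc == causal_order_chr) {
        if (is.null(gcvc_combo_sum)) gcvc_combo_sum <- numeric(ncol(s$combos))
        gcvc_combo_sum <- gcvc_combo_sum + s$gcvc
      }
    }
    best <- select_best_over_orders(scans)
    win <- best[best$overall_best, ]
    if (win$order == m_causal &&
        win$snp_ids == paste(causal, collapse = ","))
      overall_hits <- overall_hits + 1
    log_msg("replicate %d/%d done", r, n_replicates)
  }
  R <- n_replicates
  summary <- data.frame(
    order = c(orders, NA),
    scope = c(as.character(orders), "overall"),
    power = c(unname(hits) / R, overall_hits / R),
    mean_gcvc = c(unname(gsum) / R, NA),
    trtb = c(unname(trsum) / R, NA),
    tstb = c(unname(tssum) / R, NA))
  out <- list(summary = summary, n_replicates = R, model = model,
              causal_positions = causal, seed = seed, K = K, L = L)
  if (keep_gcvc_by_combo) {
    out$gcvc_by_combo <- data.frame(
      snp_ids = apply(combos_by_order[[causal_order_chr]], 2, paste,
                      collapse = ","),
      mean_gcvc = gcvc_combo_sum / R)
  }
  structure(out, class = "omdr_power")
}

#' @export
print.omdr_power <- function(x, ...) {
  cat(sprintf("omdr_power: %d replicates, causal combination (%s)\n",
              x$n_replicates, paste(x$causal_positions, collapse = ",")))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
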