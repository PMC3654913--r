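#' Full OMDR scan of a dataset over interaction orders
#'
#' The end-to-end analysis: for each order m, enumerate candidate SNP
#' combinations (exhaustively, or staged from the previous order's top
#' combinations), cross-validate every candidate, run top-K selection to
#' obtain GCVC, and finally pick the overall best classifiers across
#' orders.
#'
#' @param ds an `omdr_data` object.
#' @param orders interaction orders to scan, e.g. `1:3`.
#' @param L number of cross-validation folds (default 10).
#' @param K top-K selection size (default 1, i.e. classic CVC).
#' @param metric `"tau_b"` (default) or `"balanced_accuracy"`.
#' @param seed fold seed.
#' @param mode `"exhaustive"` (all combinations at every order) or
#'   `"staged"` (orders above the first only combine SNPs carried forward
#'   from the previous order's top `carry_k` combinations).
#' @param carry_k combinations carried forward in staged mode (default
#'   300).
#' @return an `omdr_scanset`: list with `scans` (per-order `omdr_scan`),
#'   `best` (across-order selection), `folds`, and the call parameters.
#' @examples
#' ds <- simulate_dataset(demo_interaction_model(), n = 300, p = 8, seed = 7)
#' res <- omdr_scan(ds, orders = 1:2, seed = 3)
#' res$best
#' @export
omdr_scan <- function(ds, orders = 1:2, L = 10, K = 1, metric = "tau_b",
                      seed = 1, mode = c("exhaustive", "staged"),
                      carry_k = 300) {
  validate_dataset(ds)
  mode <- match.arg(mode)
  if (length(unique(ds$phenotype)) < 2L)
    stop("phenotype has a single class; nothing to classify")
  orders <- sort(as.integer(orders))
  if (mode == "staged" &&
      !identical(orders, seq.int(orders[1], length.out = length(orders))))
    stop("staged mode requires consecutive orders")
  p <- ncol(ds$genotypes)
  folds <- make_folds(ds, L = L, seed = seed)
  scans <- list()
  prev <- NULL
  for (m in orders) {
    combos <- if (mode == "exhaustive" || is.null(prev)) {
      enumerate_exhaustive(p, m)
    } else {
      staged_candidates(prev, carry_k, m)
    }
    if (ncol(combos) == 0L) {
      log_msg("order %d: no candidates, stopping", m)
      break
    }
    log_msg("order %d: scanning %d combinations", m, ncol(combos))
    sc <- topk_select(scan_combinations(ds, combos, folds, metric = metric),
                      K = K)
    scans[[as.character(m)]] <- sc
    prev <- sc
  }
  structure(list(scans = scans,
                 best = select_best_over_orders(scans, ds$snp_ids),
                 folds = folds, orders = orders, K = K, metric = metric,
                 mode = mode, carry_k = carry_k, seed = seed),
            class = "omdr_scanset")
}

#' @export
print.omdr_scanset <- function(x, ...) {
  cat(sprintf("omdr_scanset: orders %s, K = %d, metric = %s, %d-fold CV\n",
              paste(x$orders, collapse = ","), x$K, x$metric, x$folds$L))
  cat("per-order best classifiers:\n")
  print(x$best, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' @param report a data.frame from [report_candidates()] or the `best`
#'   table of [omdr_scan()].
#' @param path output path.
#' @param header named list of run parameters written as `# key: value`
#'   comment lines (seed, folds, K, ...), for reproducibility.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, paste(header[[k]], collapse = ",")), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
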