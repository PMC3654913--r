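#' Multi-locus genotype cell index
#'
#' Encodes an m-locus genotype vector as a cell index in `1..3^m` using
#' little-endian mixed-radix base 3: cell `i = 1 + sum_k g_k * 3^(k-1)`.
#' This convention is fixed so assignments are reproducible across
#' implementations.
#'
#' @param g integer matrix (samples x m) of genotypes at the m SNPs, or a
#'   vector for a single sample.
#' @return integer vector of cell indices; `NA` where any genotype is
#'   missing.
#' @export
cell_index <- function(g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  m <- ncol(g)
  idx <- rep(1L, nrow(g))
  for (k in seq_len(m)) idx <- idx + g[, k] * 3L^(k - 1L)
  as.integer(idx)
}

#' Tabulate multi-locus genotype cells against phenotype classes
#'
#' Builds the `3^m x J` contingency table `n_ij` (individuals with the i-th
#' multi-locus genotype in class j) for a given SNP combination.  Samples
#' with a missing genotype at any of the m SNPs are dropped from this
#' table only (pairwise deletion), and the class totals `n_+j` are counted
#' over the retained samples.
#'
#' @param ds an `omdr_data` object.
#' @param snp_indices distinct, sorted column indices of the m SNPs.
#' @return an `omdr_cell_counts` object: `counts` (`3^m x J`),
#'   `class_totals` (`n_+j`), `m`, `snp_indices`, `n_dropped`.
#' @export
tabulate_cells <- function(ds, snp_indices) {
  validate_dataset(ds)
  snp_indices <- as.integer(snp_indices)
  if (anyDuplicated(snp_indices)) stop("duplicate SNP indices")
  if (is.unsorted(snp_indices, strictly = TRUE)) stop("SNP indices must be sorted")
  if (any(snp_indices < 1L | snp_indices > ncol(ds$genotypes)))
    stop("SNP index out of range")
  m <- length(snp_indices)
  J <- ds$n_classes
  g <- ds$genotypes[, snp_indices, drop = FALSE]
  cells <- cell_index(g)
  keep <- !is.na(cells)
  ncell <- 3L^m
  counts <- matrix(0L, ncell, J)
  if (any(keep)) {
    tab <- tabulate((ds$phenotype[keep] - 1L) * ncell + cells[keep],
                    nbins = ncell * J)
    counts <- matrix(tab, ncell, J)
  }
  structure(list(counts = counts, class_totals = colSums(counts),
                 m = m, snp_indices = snp_indices,
                 n_dropped = sum(!keep)),
            class = "omdr_cell_counts")
}

#' Estimated odds ratio of class j versus class 1 in one genotype cell
#'
#' The per-cell odds ratio estimate
#' \deqn{\hat\theta_{ij} = (n_{ij}/n_{i1}) / (n_{+j}/n_{+1})}
#' which compares the class-j odds within cell i to the marginal class-j
#' odds.  `NA` marks the undefined case (`n_i1 = 0` or `n_+j = 0`); the
#' class assignment itself never needs the ratio to be defined, since
#' maximizing \eqn{\hat\theta_{ij}} over j is equivalent to maximizing
#' \eqn{n_{ij}/n_{+j}}.
#'
#' @param counts an `omdr_cell_counts` object.
#' @param i cell index in `1..3^m`.
#' @param j class index in `1..J`.
#' @return the odds-ratio estimate, `1` exactly for `j = 1` when defined,
#'   or `NA` when undefined.
#' @export
estimated_or <- function(counts, i, j) {
  stopifnot(inherits(counts, "omdr_cell_counts"))
  ncell <- nrow(counts$counts)
  J <- ncol(counts$counts)
  if (i < 1 || i > ncell) stop("cell index out of range")
  if (j < 1 || j > J) stop("class index out of range")
  ni1 <- counts$counts[i, 1]
  npj <- counts$class_totals[j]
  np1 <- counts$class_totals[1]
  if (ni1 == 0 || npj == 0 || np1 == 0) return(NA_real_)
  (counts$counts[i, j] / ni1) / (npj / np1)
}

#' Assign each genotype cell to its predicted ordinal class
#'
#' Implements the OMDR reduction rule: cell i is assigned class
#' \deqn{c(i) = \arg\max_j \hat\theta_{ij} = \arg\max_j n_{ij}/n_{+j}.}
#' Ties are broken by the largest class index among the maximizers (the
#' convention the method inherits from binary MDR, where tied cells default
#' to high risk); tied cells are recorded so they can be audited.  Cells
#' with no training observations are unclassifiable and marked `NA`.
#' Classes with `n_+j = 0` are removed from the argmax.
#'
#' @param counts an `omdr_cell_counts` object with at least one non-empty
#'   class.
#' @return an `omdr_classifier` object: `assignment` (length `3^m`, values
#'   in `1..J` or `NA`), `snp_indices`, `n_classes`, `tie_cells`.
#' @export
assign_cells <- function(counts) {
  stopifnot(inherits(counts, "omdr_cell_counts"))
  tot <- counts$class_totals
  if (all(tot == 0)) stop("all class totals are zero")
  ratio <- sweep(counts$counts, 2, pmax(tot, 1L), "/")
  ratio[, tot == 0] <- -Inf
  best <- max.col(ratio, ties.method = "last")
  first <- max.col(ratio, ties.method = "first")
  occupied <- rowSums(counts$counts) > 0L
  assignment <- ifelse(occupied, best, NA_integer_)
  structure(list(assignment = as.integer(assignment),
                 snp_indices = counts$snp_indices,
                 n_classes = ncol(counts$counts),
                 tie_cells = which(occupied & best != first)),
            class = "omdr_classifier")
}

#' Fit an OMDR classifier on a dataset
#'
#' Convenience wrapper: [tabulate_cells()] then [assign_cells()].
#'
#' @inheritParams tabulate_cells
#' @return an `omdr_classifier`.
#' @examples
#' ds <- simulate_dataset(demo_interaction_model(), n = 200, p = 5, seed = 1)
#' fit_classifier(ds, c(1, 2))
#' @export
fit_classifier <- function(ds, snp_indices) {
  assign_cells(tabulate_cells(ds, snp_indices))
}

#' @export
print.omdr_classifier <- function(x, ...) {
  cat(sprintf("omdr_classifier: %d-way, SNPs (%s), J = %d\n",
              length(x$snp_indices),
              paste(x$snp_indices, collapse = ","), x$n_classes))
  cat(sprintf("cells: %d assigned, %d empty, %d ties\n",
              sum(!is.na(x$assignment)), sum(is.na(x$assignment)),
              length(x$tie_cells)))
  invisible(x)
}

#' Predict ordinal classes for a dataset
#'
#' Maps each sample through its multi-locus genotype cell to the fitted
#' class `c(i)`.  Samples whose cell was empty in training, or with a
#' missing genotype at any model SNP, are unclassified (`NA`) and later
#' excluded from the confusion matrix.
#'
#' @param object an `omdr_classifier`.
#' @param ds an `omdr_data` whose SNP universe contains the model SNPs.
#' @param ... unused.
#' @return integer vector of predicted classes (`NA` = unclassified).
#' @export
predict.omdr_classifier <- function(object, ds, ...) {
  validate_dataset(ds)
  if (any(object$snp_indices > ncol(ds$genotypes)))
    stop("model SNPs absent from dataset")
  cells <- cell_index(ds$genotypes[, object$snp_indices, drop = FALSE])
  pred <- rep(NA_integer_, length(cells))
  ok <- !is.na(cells)
  pred[ok] <- object$assignment[cells[ok]]
  pred
}

#' Confusion matrix of true versus predicted ordinal classes
#'
#' The `J x J` table with `x_jk` = number of individuals of true class j
#' predicted as class k, equivalently \eqn{x_{jk} = \sum_{i: c(i)=k} n_{ij}}.
#' Unclassified samples contribute only to `n_excluded`.
#'
#' @param truth integer vector of true classes in `1..J`.
#' @param predicted integer vector of predicted classes (`NA` =
#'   unclassified), same length.
#' @param n_classes J.
#' @return an `omdr_confusion` object: `x` (`J x J` count matrix),
#'   `n_excluded`.
#' @export
confusion <- function(truth, predicted, n_classes) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  J <- as.integer(n_classes)
  if (any(truth < 1L | truth > J, na.rm = TRUE) ||
      any(predicted < 1L | predicted > J, na.rm = TRUE))
    stop(sprintf("class labels out of range 1..%d", J))
  ok <- !is.na(predicted) & !is.na(truth)
  x <- matrix(tabulate((predicted[ok] - 1L) * J + truth[ok], nbins = J * J),
              J, J)
  structure(list(x = x, n_excluded = sum(!ok)), class = "omdr_confusion")
}

#' @export
print.omdr_confusion <- function(x, ...) {
  cat("omdr_confusion (rows = true class, cols = predicted):\n")
  print(x$x)
  if (x$n_excluded) cat("excluded (unclassified):", x$n_excluded, "\n")
  invisible(x)
}

#' Serialize a fitted classifier to JSON
#'
#' @param model an `omdr_classifier`.
#' @param snp_ids optional SNP id vector of the parent dataset, used to
#'   name the model SNPs in the document.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
classifier_to_json <- function(model, snp_ids = NULL, path = NULL) {
  stopifnot(inherits(model, "omdr_classifier"))
  doc <- list(
    snp_indices = model$snp_indices,
    snp_ids = if (!is.null(snp_ids)) snp_ids[model$snp_indices],
    n_classes = model$n_classes,
    assignment = model$assignment,
    tie_cells = as.integer(model$tie_cells))
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
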