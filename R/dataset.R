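#' Construct a genotype/phenotype dataset
#'
#' The container every other function in the package consumes: an `n x p`
#' genotype matrix coded as minor-allele counts (0/1/2, `NA` for missing)
#' together with an ordinal phenotype in classes `1..J`.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; values
#'   0, 1, 2 or `NA`.
#' @param phenotype integer vector of length `nrow(genotypes)` with values in
#'   `1..n_classes`.
#' @param snp_ids character vector of unique SNP identifiers; defaults to the
#'   matrix column names, or `SNP1..SNPp` when absent.
#' @param n_classes number of ordinal classes `J`; defaults to the largest
#'   observed phenotype label.
#' @return an object of class `omdr_data` with fields `genotypes`,
#'   `phenotype`, `snp_ids`, `n_classes`.
#' @examples
#' g <- matrix(c(0, 1, 2, 0, 1, 1, 2, 0), nrow = 4)
#' omdr_dataset(g, c(1, 2, 3, 2))
#' @export
omdr_dataset <- function(genotypes, phenotype, snp_ids = NULL,
                         n_classes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  dimnames(genotypes) <- NULL  # ids live in snp_ids; keeps equality canonical
  if (is.null(n_classes)) {
    n_classes <- if (length(phenotype)) max(phenotype) else 2L
  }
  ds <- structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_ids = as.character(snp_ids), n_classes = as.integer(n_classes)),
    class = "omdr_data")
  validate_dataset(ds)
  ds
}

#' Validate an `omdr_data` object
#'
#' Checks the container invariants: genotype values in \{0,1,2,NA\},
#' phenotype labels in `1..J`, unique SNP ids matching the genotype columns.
#'
#' @param ds an `omdr_data` object.
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "omdr_data"))
  g <- ds$genotypes
  bad <- which(!is.na(g) & !(g %in% 0:2))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(g)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(g)) + 1L
    stop(sprintf("invalid genotype value %s at sample %d, SNP '%s' (must be 0/1/2/NA)",
                 g[bad[1]], i, ds$snp_ids[j]))
  }
  if (length(ds$phenotype) != nrow(g))
    stop("phenotype length does not match number of samples")
  if (anyNA(ds$phenotype))
    stop("missing phenotype values are not supported")
  if (length(ds$phenotype) &&
      (min(ds$phenotype) < 1L || max(ds$phenotype) > ds$n_classes))
    stop(sprintf("phenotype labels must lie in 1..%d", ds$n_classes))
  if (ds$n_classes < 2L) stop("n_classes must be >= 2")
  if (anyDuplicated(ds$snp_ids)) stop("snp_ids must be unique")
  if (length(ds$snp_ids) != ncol(g))
    stop("snp_ids length does not match number of SNP columns")
  invisible(ds)
}

#' @export
print.omdr_data <- function(x, ...) {
  cat(sprintf("omdr_data: %d samples x %d SNPs, J = %d classes\n",
              nrow(x$genotypes), ncol(x$genotypes), x$n_classes))
  tab <- tabulate(x$phenotype, x$n_classes)
  cat("class counts:", paste(tab, collapse = " / "), "\n")
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss) cat("missing genotypes:", nmiss, "\n")
  invisible(x)
}

#' Collapse an ordinal phenotype to a binary one
#'
#' Maps classes `1..cut` to 1 (control) and `cut+1..J` to 2 (case), leaving
#' genotypes untouched. With the three-class trait of the simulation design
#' and `cut = 2`, classes 1-2 (normal, low risk) become controls and class 3
#' (high risk) becomes the case class, so the expected case prevalence equals
#' the class-3 prevalence.
#'
#' @param ds an `omdr_data` object.
#' @param cut threshold class, `1 <= cut < J`; classes above it become cases.
#' @return a new `omdr_data` with `n_classes = 2`.
#' @examples
#' g <- matrix(0L, 4, 1)
#' ds <- omdr_dataset(g, c(1, 2, 3, 2))
#' binarize_phenotype(ds, 2)$phenotype  # 1 1 2 1
#' @export
binarize_phenotype <- function(ds, cut) {
  validate_dataset(ds)
  cut <- as.integer(cut)
  if (cut < 1L || cut >= ds$n_classes)
    stop(sprintf("cut must satisfy 1 <= cut < J = %d", ds$n_classes))
  omdr_dataset(ds$genotypes,
               ifelse(ds$phenotype <= cut, 1L, 2L),
               snp_ids = ds$snp_ids, n_classes = 2L)
}
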