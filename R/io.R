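#' Read a genotype/phenotype dataset from tab-delimited text
#'
#' The file dialect is one header row and one sample per row: SNP columns
#' coded as minor-allele counts 0/1/2 (missing as `NA`), plus one named
#' phenotype column with integer class labels `1..J`.  This matches PLINK
#' `.raw` additive coding, so real genotype data can be converted with
#' standard tools.
#'
#' @param path path to a TSV file.
#' @param phenotype_column name of the phenotype column (default
#'   `"phenotype"`).
#' @param n_classes number of ordinal classes; if `NULL`, inferred as the
#'   largest observed label (a message records the inference).
#' @return an `omdr_data` object.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, phenotype_column = "phenotype",
                         n_classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (!phenotype_column %in% names(df))
    stop(sprintf("phenotype column '%s' not found in %s",
                 phenotype_column, path))
  snp_cols <- setdiff(names(df), phenotype_column)
  g <- matrix(NA_integer_, nrow(df), length(snp_cols),
              dimnames = list(NULL, snp_cols))
  for (j in seq_along(snp_cols)) {
    v <- df[[snp_cols[j]]]
    ok <- is.na(v) | v %in% c("0", "1", "2")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("malformed genotype value '%s' at row %d, column '%s'",
                   v[i], i, snp_cols[j]))
    }
    g[, j] <- as.integer(v)
  }
  ph <- suppressWarnings(as.integer(df[[phenotype_column]]))
  if (nrow(df) && anyNA(ph))
    stop("non-integer phenotype value in column ", phenotype_column)
  if (is.null(n_classes)) {
    n_classes <- if (length(ph)) max(ph) else 2L
    message(sprintf("n_classes not given; inferred J = %d from data",
                    n_classes))
  }
  omdr_dataset(g, ph, snp_ids = snp_cols, n_classes = n_classes)
}

#' Write a dataset as tab-delimited text
#'
#' Writes the dialect read by [read_dataset()]: SNP columns named by
#' `snp_ids`, the phenotype in a `phenotype` column, missing genotypes as
#' `NA`.  `read_dataset(write_dataset(ds))` reproduces `ds` exactly.
#'
#' @param ds an `omdr_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  df <- as.data.frame(ds$genotypes)
  names(df) <- ds$snp_ids
  df$phenotype <- ds$phenotype
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
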