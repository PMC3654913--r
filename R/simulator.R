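#' Hardy-Weinberg genotype frequencies
#'
#' Genotype probabilities for 0/1/2 copies of the minor allele at
#' frequency `q` under random mating: `((1-q)^2, 2q(1-q), q^2)`.
#'
#' @param maf minor allele frequency, in `(0, 0.5]`.
#' @return numeric vector of length 3 summing to 1.
#' @examples
#' hwe_genotype_freqs(0.3)  # 0.49 0.42 0.09
#' @export
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must be in (0, 0.5]")
  q <- maf
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Penetrance table from per-genotype odds ratios
#'
#' Converts a table of odds ratios of class j versus class 1 per causal
#' multi-locus genotype into class probabilities ("penetrances"): row i is
#' proportional to `theta_ij * p_j / p_1` and normalized to sum to 1.
#' With all odds ratios equal to 1 every row reduces to the prevalence
#' vector exactly, so the null model leaves the phenotype independent of
#' genotype.  The mapping is self-consistent: odds ratios recomputed from
#' expected counts under the resulting penetrances recover the input
#' table.
#'
#' @param or_table numeric matrix, rows = multi-locus genotypes (mixed-radix
#'   cell order, see [cell_index()]), columns = classes; column 1 must be
#'   identically 1.
#' @param prevalences positive class prevalences summing to 1.
#' @return penetrance matrix of the same shape, rows summing to 1.
#' @export
penetrance_from_ors <- function(or_table, prevalences) {
  or_table <- as.matrix(or_table)
  if (any(or_table < 0)) stop("odds ratios must be nonnegative")
  if (any(abs(or_table[, 1] - 1) > 1e-12))
    stop("column 1 of the odds-ratio table must be 1 (baseline class)")
  check_prevalences(prevalences, ncol(or_table))
  w <- sweep(or_table, 2, prevalences / prevalences[1], "*")
  sweep(w, 1, rowSums(w), "/")
}

check_prevalences <- function(p, J) {
  if (length(p) != J) stop("prevalence vector length must equal J")
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-9)
    stop("prevalences must be positive and sum to 1")
  invisible(p)
}

#' Specify a genetic model for the simulator
#'
#' A simulation model: number of ordinal classes, their population
#' prevalences, minor allele frequencies of the causal SNPs, and either a
#' per-genotype odds-ratio table (converted via [penetrance_from_ors()])
#' or an explicit penetrance table.  When both are given the explicit
#' penetrances win.
#'
#' @param prevalences class prevalences `p_j`, positive, summing to 1.
#' @param mafs minor allele frequencies of the causal SNPs (length = number
#'   of causal SNPs).
#' @param or_table odds-ratio matrix (`3^m_c x J`, column 1 all ones), or
#'   `NULL`.
#' @param penetrance explicit penetrance matrix (`3^m_c x J`, rows summing
#'   to 1), or `NULL`; overrides `or_table`.
#' @param pattern_id optional label for the interaction pattern.
#' @return an `omdr_model` object with fields `J`, `prevalences`, `mafs`,
#'   `penetrance`, `or_table`, `pattern_id`.
#' @export
genetic_model <- function(prevalences, mafs, or_table = NULL,
                          penetrance = NULL, pattern_id = NULL) {
  J <- length(prevalences)
  check_prevalences(prevalences, J)
  for (q in mafs) hwe_genotype_freqs(q)  # range check
  ncell <- 3L^length(mafs)
  if (is.null(penetrance)) {
    if (is.null(or_table)) stop("give or_table or penetrance")
    penetrance <- penetrance_from_ors(or_table, prevalences)
  } else {
    penetrance <- as.matrix(penetrance)
    if (any(penetrance < 0) || any(abs(rowSums(penetrance) - 1) > 1e-9))
      stop("penetrance rows must be probabilities summing to 1")
  }
  if (nrow(penetrance) != ncell || ncol(penetrance) != J)
    stop(sprintf("penetrance table must be %d x %d for %d causal SNPs",
                 ncell, J, length(mafs)))
  structure(list(J = as.integer(J), prevalences = as.numeric(prevalences),
                 mafs = as.numeric(mafs), penetrance = penetrance,
                 or_table = or_table, pattern_id = pattern_id),
            class = "omdr_model")
}

#' @export
print.omdr_model <- function(x, ...) {
  cat(sprintf("omdr_model: J = %d, %d causal SNP(s), MAFs (%s)%s\n",
              x$J, length(x$mafs), paste(x$mafs, collapse = ", "),
              if (!is.null(x$pattern_id)) paste0(", pattern ", x$pattern_id) else ""))
  cat("prevalences:", paste(x$prevalences, collapse = " / "), "\n")
  invisible(x)
}

#' Null (no-effect) genetic model
#'
#' All per-genotype odds ratios equal to 1, so every penetrance row equals
#' the prevalence vector and the phenotype is independent of every SNP.
#' Defaults follow the three-class simulation design: prevalences
#' 0.3/0.4/0.3 and causal-slot MAFs 0.3 and 0.5.
#'
#' @param prevalences class prevalences.
#' @param mafs MAFs of the (inert) causal-slot SNPs.
#' @return an `omdr_model`.
#' @export
null_model <- function(prevalences = c(0.3, 0.4, 0.3), mafs = c(0.3, 0.5)) {
  J <- length(prevalences)
  ncell <- 3L^length(mafs)
  genetic_model(prevalences, mafs,
                or_table = matrix(1, ncell, J), pattern_id = "null")
}

#' Demonstration two-locus interaction model
#'
#' A strong checkerboard-style two-way interaction for a three-class trait:
#' the penetrance row of each two-locus genotype depends on the parity of
#' the summed minor-allele counts at the two loci, so neither SNP has a
#' strong marginal effect but the pair is highly informative.  Causal MAFs
#' are 0.3 and 0.5 and prevalences 0.3/0.4/0.3, matching the simulation
#' design this generator emulates.  Intended for examples, power checks
#' and as a template for user-defined models.
#'
#' @return an `omdr_model`.
#' @export
demo_interaction_model <- function() {
  rows <- rbind(c(0.6, 0.3, 0.1),
                c(0.2, 0.6, 0.2),
                c(0.1, 0.3, 0.6))
  pen <- matrix(0, 9, 3)
  for (g1 in 0:2) for (g2 in 0:2) {
    pen[1 + g1 + 3 * g2, ] <- rows[(g1 + g2) %% 3 + 1, ]
  }
  genetic_model(c(0.3, 0.4, 0.3), mafs = c(0.3, 0.5), penetrance = pen,
                pattern_id = "demo-checkerboard")
}

#' Marginal class probabilities implied by a genetic model
#'
#' Diagnostic: the population class distribution
#' `P(j) = sum_i P(i) p_{j|i}` implied by HWE genotype frequencies and the
#' penetrance table; any drift from the target prevalences (possible when
#' explicit penetrances are supplied) is visible here.
#'
#' @param model an `omdr_model`.
#' @return numeric vector of length `J` summing to 1.
#' @export
implied_prevalences <- function(model) {
  stopifnot(inherits(model, "omdr_model"))
  freqs <- lapply(model$mafs, hwe_genotype_freqs)
  ncell <- nrow(model$penetrance)
  pcell <- numeric(ncell)
  mc <- length(model$mafs)
  for (i in seq_len(ncell)) {
    g <- cell_genotypes(i, mc)
    pcell[i] <- prod(vapply(seq_len(mc),
                            function(k) freqs[[k]][g[k] + 1L], 0))
  }
  as.numeric(pcell %*% model$penetrance)
}

# decode cell index (1-based, little-endian base 3) to genotype vector
cell_genotypes <- function(i, m) {
  g <- integer(m)
  v <- i - 1L
  for (k in seq_len(m)) {
    g[k] <- v %% 3L
    v <- v %/% 3L
  }
  g
}

#' Simulate one genotype/phenotype dataset
#'
#' Prospective (population) sampling: every SNP's genotypes are drawn
#' independently from its HWE frequencies; each sample's phenotype is
#' drawn from the penetrance row of its causal multi-locus genotype, so
#' class counts are multinomial around the model-implied marginals rather
#' than fixed by design.  Non-causal SNPs are independent of the
#' phenotype.  Deterministic given `seed`.
#'
#' @param model an `omdr_model`.
#' @param n samples per dataset (default 1000, the simulation-design
#'   replicate size).
#' @param p total SNPs including causal ones (default 50).
#' @param causal_positions column positions of the causal SNPs (default
#'   the first `length(model$mafs)` columns).
#' @param noncausal_maf MAF for every non-causal SNP (default 0.3), or a
#'   vector recycled over them.
#' @param seed integer seed.
#' @return an `omdr_data`; the causal positions are attached as attribute
#'   `causal_positions`.
#' @export
simulate_dataset <- function(model, n = 1000, p = 50,
                             causal_positions = seq_along(model$mafs),
                             noncausal_maf = 0.3, seed = 1) {
  stopifnot(inherits(model, "omdr_model"))
  mc <- length(model$mafs)
  causal_positions <- as.integer(causal_positions)
  if (length(causal_positions) != mc || anyDuplicated(causal_positions) ||
      any(causal_positions < 1L | causal_positions > p))
    stop("causal_positions must be distinct positions in 1..p for each causal SNP")
  g <- matrix(NA_integer_, n, p)
  with_seed(seed, {
    maf_all <- rep_len(noncausal_maf, p)
    maf_all[causal_positions] <- model$mafs
    for (j in seq_len(p)) {
      g[, j] <- sample(0:2, n, replace = TRUE,
                       prob = hwe_genotype_freqs(maf_all[j]))
    }
    cells <- cell_index(g[, causal_positions, drop = FALSE])
    y <- integer(n)
    for (i in seq_len(3L^mc)) {
      idx <- which(cells == i)
      if (length(idx))
        y[idx] <- sample.int(model$J, length(idx), replace = TRUE,
                             prob = model$penetrance[i, ])
    }
  })
  ds <- omdr_dataset(g, y, n_classes = model$J)
  attr(ds, "causal_positions") <- sort(causal_positions)
  ds
}

#' Child seed for replicate r
#'
#' Deterministic derivation of an independent replicate seed from the
#' master seed, kept below 2^31 so it is a valid R integer seed.
#'
#' @param master master integer seed.
#' @param r replicate index (1-based).
#' @return integer seed.
#' @export
child_seed <- function(master, r) {
  as.integer((as.numeric(master) * 1009 + r) %% 2147483647)
}

#' Simulate replicate datasets
#'
#' Replicate `r` uses [child_seed()]`(seed, r)`, so any single replicate
#' can be regenerated on its own and the stream is independent of
#' generation order.
#'
#' @inheritParams simulate_dataset
#' @param n_replicates number of replicate datasets (the simulation design
#'   uses 100).
#' @param seed master seed.
#' @param FUN optional callback applied to each dataset; when given, the
#'   list of `FUN` results is returned instead of the datasets (useful to
#'   avoid holding all replicates in memory).
#' @return list of `omdr_data` (or of `FUN` results), length
#'   `n_replicates`.
#' @export
simulate_replicates <- function(model, n_replicates = 100, n = 1000, p = 50,
                                causal_positions = seq_along(model$mafs),
                                noncausal_maf = 0.3, seed = 1, FUN = NULL) {
  lapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(model, n = n, p = p,
                           causal_positions = causal_positions,
                           noncausal_maf = noncausal_maf,
                           seed = child_seed(seed, r))
    if (is.null(FUN)) ds else FUN(ds, r)
  })
}

#' Load a genetic model from a JSON spec file
#'
#' The spec format has keys `classes`, `prevalences`, `mafs`,
#' `genotype_rows` (a list of objects with `genotype` = the per-locus
#' minor-allele counts and either `or` or `penetrance` vectors of length
#' `classes`), and optional `pattern_id`.  Every multi-locus genotype of
#' the causal SNPs must appear exactly once.
#'
#' @param path path to the JSON file.
#' @return an `omdr_model`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec not found: ", path)
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  J <- as.integer(spec$classes)
  mafs <- as.numeric(spec$mafs)
  mc <- length(mafs)
  ncell <- 3L^mc
  rows <- spec$genotype_rows
  if (length(rows) != ncell)
    stop(sprintf("expected %d genotype rows, found %d", ncell, length(rows)))
  or_tab <- matrix(NA_real_, ncell, J)
  pen_tab <- matrix(NA_real_, ncell, J)
  seen <- logical(ncell)
  for (row in rows) {
    g <- as.integer(row$genotype)
    if (length(g) != mc || any(g < 0 | g > 2))
      stop("genotype_rows entries must give minor-allele counts for each causal SNP")
    i <- cell_index(g)
    if (seen[i]) stop("duplicate genotype row: ", paste(g, collapse = "/"))
    seen[i] <- TRUE
    if (!is.null(row$penetrance)) pen_tab[i, ] <- as.numeric(row$penetrance)
    if (!is.null(row$or)) or_tab[i, ] <- as.numeric(row$or)
  }
  if (!all(seen)) {
    miss <- which(!seen)[1]
    stop("missing genotype row for genotype ",
         paste(cell_genotypes(miss, mc), collapse = "/"))
  }
  has_pen <- !anyNA(pen_tab)
  has_or <- !anyNA(or_tab)
  if (!has_pen && !has_or)
    stop("every genotype row needs an 'or' or a 'penetrance' vector")
  genetic_model(as.numeric(spec$prevalences), mafs,
                or_table = if (has_or) or_tab else NULL,
                penetrance = if (has_pen) pen_tab else NULL,
                pattern_id = spec$pattern_id)
}

#' Write a genetic model as a JSON spec file
#'
#' @param model an `omdr_model`.
#' @param path output path.
#' @param use_or write the odds-ratio table (if present) instead of
#'   penetrances.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path, use_or = FALSE) {
  stopifnot(inherits(model, "omdr_model"))
  mc <- length(model$mafs)
  rows <- lapply(seq_len(nrow(model$penetrance)), function(i) {
    row <- list(genotype = cell_genotypes(i, mc))
    if (use_or && !is.null(model$or_table)) {
      row$or <- as.numeric(model$or_table[i, ])
    } else {
      row$penetrance <- as.numeric(model$penetrance[i, ])
    }
    row
  })
  doc <- list(classes = model$J, prevalences = model$prevalences,
              mafs = model$mafs, genotype_rows = rows,
              pattern_id = model$pattern_id)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}
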