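test_that("Hardy-Weinberg genotype frequencies follow the closed form", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0.3), c(0.49, 0.42, 0.09))
  for (q in c(0.01, 0.17, 0.33, 0.5))
    expect_equal(sum(hwe_genotype_freqs(q)), 1)
  expect_error(hwe_genotype_freqs(0), "maf")
  expect_error(hwe_genotype_freqs(0.7), "maf")
})

test_that("odds ratios convert to penetrances by prevalence-weighted normalization", {
  prev <- c(0.3, 0.4, 0.3)
  # all theta = 1: penetrance rows equal the prevalences exactly
  pen_null <- penetrance_from_ors(matrix(1, 9, 3), prev)
  for (i in 1:9) expect_equal(pen_null[i, ], prev)
  # hand-normalized single row: theta (1,2,1) -> (0.3,0.8,0.3)/1.4
  pen <- penetrance_from_ors(matrix(c(1, 2, 1), 1, 3), prev)
  expect_equal(pen[1, ], c(3, 8, 3) / 14, tolerance = 1e-12)
  expect_error(penetrance_from_ors(matrix(c(1, -2, 1), 1, 3), prev),
               "nonnegative")
  expect_error(penetrance_from_ors(matrix(c(2, 2, 1), 1, 3), prev),
               "baseline")
})

test_that("expected counts under the generated penetrances are consistent with the input ORs", {
  # Within every genotype cell the class odds against the baseline class
  # are exactly theta_ij * p_j/p_1, so the ratio-of-ratios recomputed with
  # the *target* prevalence ratio in the denominator recovers theta
  # exactly.  Recomputing it against the expected marginal class totals
  # recovers theta up to one constant per class (the implied marginals
  # drift from the target prevalences for unbalanced OR patterns); in the
  # null case that constant is 1.
  set.seed(103)
  prev <- c(0.3, 0.4, 0.3)
  or_tab <- cbind(1, matrix(runif(18, 0.25, 4), 9, 2))
  model <- genetic_model(prev, mafs = c(0.3, 0.5), or_table = or_tab)
  freqs1 <- hwe_genotype_freqs(0.3)
  freqs2 <- hwe_genotype_freqs(0.5)
  pcell <- as.vector(outer(freqs1, freqs2))  # little-endian cell order
  expected_counts <- model$penetrance * pcell  # n_ij up to a constant
  n_plus <- colSums(expected_counts)
  for (j in 2:3) {
    # exact recovery against the target prevalence ratio
    theta_prev <- (expected_counts[, j] / expected_counts[, 1]) /
      (prev[j] / prev[1])
    expect_equal(theta_prev, or_tab[, j], tolerance = 1e-9)
    # Eq.-1-style estimate against expected marginals: same table up to a
    # cell-independent per-class factor
    theta_marg <- (expected_counts[, j] / expected_counts[, 1]) /
      (n_plus[j] / n_plus[1])
    ratio <- theta_marg / or_tab[, j]
    expect_lt(max(ratio) - min(ratio), 1e-9)
  }
  # null model: implied marginals equal prevalences, recovery is exact
  null_pen <- penetrance_from_ors(matrix(1, 9, 3), prev)
  null_counts <- null_pen * pcell
  null_plus <- colSums(null_counts)
  for (j in 2:3) {
    expect_equal((null_counts[, j] / null_counts[, 1]) /
                   (null_plus[j] / null_plus[1]),
                 rep(1, 9), tolerance = 1e-12)
  }
})

test_that("model construction validates shapes and probabilities", {
  expect_error(genetic_model(c(0.5, 0.6), mafs = 0.3,
                             or_table = matrix(1, 3, 2)), "sum to 1")
  expect_error(genetic_model(c(0.5, 0.5), mafs = 0.3,
                             penetrance = matrix(c(0.5, 0.2), 3, 2)),
               "summing to 1")
  expect_error(genetic_model(c(0.5, 0.5), mafs = c(0.3, 0.5),
                             or_table = matrix(1, 3, 2)), "penetrance table")
  m <- null_model()
  expect_equal(m$penetrance[5, ], c(0.3, 0.4, 0.3))
  expect_equal(implied_prevalences(m), c(0.3, 0.4, 0.3), tolerance = 1e-12)
})

test_that("simulated data is deterministic and honours genotype frequencies", {
  model <- null_model()
  d1 <- simulate_dataset(model, n = 500, p = 10, seed = 7)
  d2 <- simulate_dataset(model, n = 500, p = 10, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(model, n = 500, p = 10, seed = 8)
  expect_false(identical(d1$genotypes, d3$genotypes))
  expect_equal(attr(d1, "causal_positions"), c(1L, 2L))

  # genotype frequencies at a MAF-0.5 causal SNP around (0.25, 0.5, 0.25)
  big <- simulate_dataset(model, n = 20000, p = 3, seed = 9)
  freq <- tabulate(big$genotypes[, 2] + 1L, 3) / 20000
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 3 * sqrt(0.25 / 20000) + 0.01)
})

test_that("phenotypes follow the penetrance rows of the causal genotype", {
  model <- demo_interaction_model()
  ds <- simulate_dataset(model, n = 20000, p = 4, seed = 11)
  cells <- cell_index(ds$genotypes[, 1:2])
  for (i in c(1, 5, 9)) {
    idx <- which(cells == i)
    emp <- tabulate(ds$phenotype[idx], 3) / length(idx)
    p <- model$penetrance[i, ]
    expect_lt(max(abs(emp - p)), 3 * sqrt(max(p * (1 - p)) / length(idx)))
  }
})

test_that("replicate streams are seed-derived, independent and regenerable", {
  model <- null_model()
  reps <- simulate_replicates(model, n_replicates = 4, n = 50, p = 4,
                              seed = 21)
  expect_equal(length(reps), 4)
  for (a in 1:3) for (b in (a + 1):4)
    expect_false(identical(reps[[a]]$genotypes, reps[[b]]$genotypes))
  # replicate 3 regenerated alone equals replicate 3 of the stream
  alone <- simulate_dataset(model, n = 50, p = 4, seed = child_seed(21, 3))
  expect_identical(alone, reps[[3]])
  # callback form returns FUN results
  ns <- simulate_replicates(model, n_replicates = 2, n = 30, p = 3,
                            seed = 5, FUN = function(ds, r) nrow(ds$genotypes))
  expect_equal(unlist(ns), c(30, 30))
})

test_that("model specs round-trip through JSON in both representations", {
  model <- demo_interaction_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(model, path)
  back <- load_model_spec(path)
  expect_equal(back$penetrance, model$penetrance, tolerance = 1e-12)
  expect_equal(back$prevalences, model$prevalences)
  expect_equal(back$mafs, model$mafs)

  # a model given as ORs and the same model given as penetrances agree
  prev <- c(0.3, 0.4, 0.3)
  or_tab <- cbind(1, matrix(c(2, 0.5, 1, 3, 1, 1, 0.25, 2, 1.5,
                              1, 2, 3, 0.5, 1, 2, 3, 1, 0.5), 9, 2))
  m_or <- genetic_model(prev, c(0.3, 0.5), or_table = or_tab)
  p_or <- withr::local_tempfile(fileext = ".json")
  p_pen <- withr::local_tempfile(fileext = ".json")
  write_model_spec(m_or, p_or, use_or = TRUE)
  write_model_spec(m_or, p_pen, use_or = FALSE)
  expect_equal(load_model_spec(p_or)$penetrance,
               load_model_spec(p_pen)$penetrance, tolerance = 1e-9)

  # malformed: missing genotype row
  spec <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = FALSE)
  spec$genotype_rows <- spec$genotype_rows[-4]
  p_bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE), p_bad)
  expect_error(load_model_spec(p_bad), "genotype rows")
})

test_that("null simulation matches target prevalences and binarized case rate", {
  ds <- simulate_dataset(null_model(), n = 10000, p = 5, seed = 31)
  prop <- tabulate(ds$phenotype, 3) / 10000
  se <- sqrt(c(0.3, 0.4, 0.3) * c(0.7, 0.6, 0.7) / 10000)
  expect_true(all(abs(prop - c(0.3, 0.4, 0.3)) < 3 * se))
  bin <- binarize_phenotype(ds, 2)
  case_rate <- mean(bin$phenotype == 2)
  expect_lt(abs(case_rate - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # case rate equals the model-implied class-3 mass exactly by construction
  expect_equal(case_rate, prop[3])
})
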