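---
title: "Ordinal MDR: model, selection statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal MDR: model, selection statistics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omdr)
```

## The problem

Complex traits are shaped by interacting loci, and a pair of SNPs can carry a
signal that neither shows marginally (epistasis).  Multifactor dimensionality
reduction (MDR) detects such interactions for binary traits by pooling
multi-locus genotype cells into "high risk" and "low risk" groups and treating
the pooled variable as a one-dimensional classifier.  Many phenotypes,
however, are *ordinal* — obesity classes from BMI, glucose-tolerance stages,
disease-severity grades — and dichotomizing them throws away the ordering.
This package implements the ordinal extension (OMDR): each multi-locus
genotype cell is assigned one of the J ordered classes, classifiers are scored
with an ordinal association measure, and a generalized cross-validation
consistency statistic reports *multiple* best interactions rather than a
single winner.

## The classifier

For an m-way interaction, samples fall into the $3^m$ cells of the genotype
contingency table (cells are indexed little-endian base 3 over the m SNPs,
`cell_index()`, a convention fixed so assignments are reproducible).  With
$n_{ij}$ the number of training samples in cell $i$ and class $j$, and
$n_{+j}$ the class totals, the estimated odds ratio of class $j$ against the
baseline class 1 in cell $i$ is

$$\hat\theta_{ij} = \frac{n_{ij}/n_{i1}}{n_{+j}/n_{+1}},$$

and the cell is assigned the class

$$c(i) = \arg\max_j \hat\theta_{ij} = \arg\max_j \frac{n_{ij}}{n_{+j}}.$$

The second form is what the code maximizes: it is defined even when
$n_{i1} = 0$, and for fixed $i$ the two criteria differ by a positive factor
only.  Ties are broken toward the **largest** class index — the ordinal
analogue of binary MDR's "ties go to high risk" — and tied cells are recorded
(`tie_cells`) so they can be audited.  With $J = 2$ the rule reduces exactly
to classic binary MDR with the case:control-ratio threshold; the test suite
verifies this against an independently coded binary MDR.

Three degenerate situations are handled explicitly:

* **Empty training cells** are unclassifiable; test samples that land in them
  are excluded from scoring and counted (`n_excluded`) rather than being
  defaulted to a class.  Defaulting to "high risk" has no ordinal analogue,
  and exclusion keeps the confusion matrix honest about coverage.
* **Missing genotypes** are handled by pairwise deletion: a sample is dropped
  only from the contingency tables of combinations that touch its missing
  SNPs.  This keeps exhaustive scans from discarding whole samples.
* **Classes absent from a training fold** ($n_{+j} = 0$) are removed from the
  argmax; stratified folds (the default) make this rare.

## Evaluation: Kendall's tau-b

Classification quality is the concordance between true and predicted classes
in the $J \times J$ confusion matrix $x_{jk} = \sum_{i\,:\,c(i)=k} n_{ij}$,
measured by Kendall's tau-b:

$$\tau_b = \frac{P - Q}{\sqrt{(N_0 - T_r)(N_0 - T_c)}},$$

with $P$/$Q$ the concordant/discordant pair counts, $N_0 = n(n-1)/2$, and
$T_r$, $T_c$ the tied-pair counts from the row and column totals.  It is
computed in closed form from cell products — $O(J^4)$ per table and exact —
never by expanding to per-sample vectors; a brute-force pair-enumeration
oracle confirms equality on thousands of random tables.  A table with all
mass in one row or column carries no ordinal information: its tau-b is
undefined (`NA`) and ranks below any defined value.  Unclassified samples are
omitted and `n_effective` is reported, so low-coverage classifiers remain
visible.  Balanced accuracy (macro-averaged recall) is provided as the
conventional binary baseline.

## Cross-validation, top-K selection and GCVC

The data are split into $L$ stratified folds (default $L = 10$).  For each
fold, every candidate combination is fitted on the other $L-1$ folds and
scored on both the training and the held-out part.  Within each fold the $K$
combinations with the largest *training* metric are flagged
($I_l \in \{0,1\}$), and each combination's generalized cross-validation
consistency is

$$\mathrm{GCVC}^K = \sum_{l=1}^{L} I_l \in \{0, \dots, L\},$$

the number of folds that place it in the top K.  $K = 1$ recovers the classic
CVC.  Ties at the rank-K boundary are broken toward the lexicographically
smallest SNP combination — the statistic must be reproducible, so the
boundary cannot admit more than K winners.  Three reporting criteria are
implemented (`report_candidates()`): every combination with
$\mathrm{GCVC}^K > 0$ (exploratory), $\mathrm{GCVC}^K \ge c$ (e.g. 9 of 10
folds, high selection confidence), and the top-N list.

Where "maximum predictability" and "maximum GCVC" disagree, GCVC is primary
*within* an order (it is the selection-stability criterion) and the mean test
metric is primary *across* orders (it is the predictability headline), with
ties going to larger GCVC and then to the smaller order (parsimony).  Both
rankings are exposed, so users can apply their own rule.  Per-fold top-K
selection uses the training metric, and training tau-b is computed on the
training fold's own confusion matrix (no refit).

The exhaustive search enumerates all $\binom{p}{m}$ combinations; the staged
search for large panels carries the SNPs of the top `carry_k` combinations at
order $m-1$ forward (ranked by the same (GCVC, mean test) key as reporting)
and enumerates m-subsets of that pool.  Candidates are materialized as an
integer matrix and processed in fixed-size chunks by the scan engine, which
tabulates every contingency table of a fold in a single `tabulate()` pass;
the chunking bounds memory the way a streaming generator would.

## The simulator

The generator emulates a population study of a three-class ordinal trait:
prevalences $p = (0.3, 0.4, 0.3)$, 50 SNPs of which one pair is causal with a
two-way interaction, causal minor allele frequencies 0.3 and 0.5, $n = 1000$
samples per replicate, 100 replicates per model (scaled-down runs use fewer —
the package's checks use 20 replicates for power studies, which bounds a
two-locus power study to roughly a minute per model on one core).  Genotypes
are drawn per SNP from Hardy–Weinberg frequencies
$((1-q)^2,\, 2q(1-q),\, q^2)$; each sample's phenotype is drawn from the
penetrance row $p_{j|i}$ of its causal two-locus genotype; non-causal SNPs
(default MAF 0.3, a typical common-variant frequency, overridable) are
independent of the phenotype.  Sampling is prospective: class counts are
multinomial around the model-implied marginals, not fixed by design.

Models are specified either by explicit penetrances or by per-genotype odds
ratios $\theta_{ij}$ of class $j$ versus class 1, converted by

$$p_{j|i} \propto \theta_{ij}\,\frac{p_j}{p_1}, \qquad \sum_j p_{j|i} = 1.$$

With all $\theta = 1$ every row equals the prevalence vector exactly, so the
null model leaves the phenotype independent of every SNP.  One property of
this mapping deserves care: the within-cell odds against the *target*
prevalence ratio reproduce $\theta_{ij}$ exactly, but the Eq.-style odds
ratio recomputed against the *realized marginal* class totals recovers the
input table only up to one constant per class, because row normalization
lets the implied marginals drift from the target prevalences for unbalanced
patterns.  Enforcing exact marginals and exact odds ratios simultaneously is
overdetermined, so the simple proportional rule is used, the drift is
reported by `implied_prevalences()`, and explicitly loaded penetrances always
win over a derivation from odds ratios.

Replicate $r$ uses the child seed $(1009\,s + r) \bmod (2^{31}-1)$ of the
master seed $s$, so any replicate can be regenerated alone and results do not
depend on generation order.  Fold plans are re-randomized per replicate.

What the simulator does *not* emulate: linkage disequilibrium between SNPs,
covariates, family structure, genotyping error, and missingness patterns of
real panels.  Passing power checks on these data therefore show that the
pipeline recovers a planted interaction under clean, independent-SNP
conditions — not that it is robust to confounding in real cohorts.

## Demonstration model

`demo_interaction_model()` is the package's strong two-way pattern: the
penetrance row of each two-locus genotype is one of
$(0.6, 0.3, 0.1)$, $(0.2, 0.6, 0.2)$, $(0.1, 0.3, 0.6)$, keyed to
$(g_1 + g_2) \bmod 3$.  The checkerboard layout gives the pair strong joint
information while each SNP's marginal class distribution stays close to
uniform shifts, the regime MDR-type methods are built for.  It was designed
as a fixed demonstration setting, not calibrated to any published table.

```{r}
model <- demo_interaction_model()
round(implied_prevalences(model), 3)
ds <- simulate_dataset(model, n = 600, p = 8, seed = 17)
res <- omdr_scan(ds, orders = 1:2, L = 10, seed = 4)
res$best
```

The two-locus row should name `SNP1,SNP2` with GCVC 10/10 and mean test
tau-b around 0.4; the single-locus row shows the weak marginal signal.

## Numerical choices

* Cell ratios $n_{ij}/n_{+j}$ are compared as doubles; with integer counts
  the ratios are rationals with denominators $\le n$, whose order doubles
  represent faithfully, so float comparison equals exact comparison.
* Undefined metric values (`NA`) are excluded from fold means and counted
  (`n_defined_folds`); a combination undefined in all folds ranks last.
* `make_folds()` is deterministic given its seed and restores the caller's
  RNG state, as do all simulation entry points.

## Limitations

* GCVC has no attached significance test here; permutation-based calibration
  of $\mathrm{GCVC}^K$ under the null is out of scope.
* Covariate adjustment and quantitative-trait extensions are not provided.
* The staged search is a heuristic: combinations of SNPs that only shine at
  higher orders can be missed, exactly as in the staged analyses it mirrors.
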