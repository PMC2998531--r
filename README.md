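# mhc2pred

Prediction and benchmarking of peptide binding to MHC class II molecules
(HLA-DR, -DP, -DQ and mouse class II), built around positional-scanning
combinatorial peptide libraries and a similarity-aware cross-validation
harness.

CD4+ T-cell epitope discovery starts with predicting which peptides bind a
given class II molecule. Binding is dominated by a nine-residue core sitting
in the binding groove, so a molecule's specificity can be summarised as a
9 × 20 scoring matrix *m(p, a)* of positive multiplicative weights — one per
core position *p* = 1..9 and residue *a*. The matrix is oriented like an
IC50: the predicted score of a 9-mer core is the product

    score(core) = ∏ₚ m(p, core[p])

and a longer peptide is scored by its best (lowest-scoring) 9-mer window.
Peptides with measured IC50 < 1000 nM are classified as binders.

The package is aimed at immunoinformaticians who need to (a) turn
combinatorial-library panels into predictors, (b) benchmark binding
predictors honestly in the presence of homologous peptides, and (c) combine
several predictors into a consensus.

## What it does

* **Combinatorial-library matrices** — `library_design()` enumerates the 180
  fixed-residue mixtures (13-mers, alanines at template positions 1, 2, 12,
  13); `derive_matrix()` converts a panel of 180 mixture IC50s into a scoring
  matrix by the average-relative-binding (ARB) recipe: standardise by the
  panel geometric mean, normalise each position so its optimum is 1, then
  weight positions by ARB ratios. `predict_peptides()` scans 9-mer cores.
* **Similarity and redundancy reduction** — two peptides are *similar* if
  they share a 9-mer subsequence or exceed 80% ungapped identity
  (`is_similar()`). `similarity_reduce()` builds the ALL ⊇ SR ⊇ SP dataset
  hierarchy: binder and non-binder partitions are reduced independently by a
  deterministic forward Hobohm-1 algorithm (`hobohm_reduce()`), with a
  seed-unstable `random_reduce()` comparator; `singular_peptides()` extracts
  the SP set.
* **Evaluation harness** — `make_folds()`, `cross_validate()`, `roc_auc()`
  (tie-aware threshold sweep, equal to the Mann–Whitney U with half credit),
  `spearman_rho()`, and `sp_impact_analysis()`, which compares ALL-trained
  vs SR-trained blinded predictions on the SP set with a paired t-test.
* **Baseline trainable predictor** — `train_core_matrix()`, a deterministic
  iterative best-core estimator giving the harness a machine-learning method;
  any model implementing `predict_many()` can be evaluated.
* **Median-rank consensus** — `percentile_rank()`,
  `median_rank_consensus()`, `leave_one_out_consensus()` and
  `subset_consensus()` (best-subset with per-allele fallback).
* **Synthetic data** — `synthetic_world()`, `simulate_matrix()`,
  `simulate_dataset()` (controlled homolog clusters: overlapping 15-mer
  tiles, substitution scans, near-identical variants) and
  `simulate_library_panel()` make every stage testable without downloads.

All user-facing functions take and return tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods. A command-line front end is
installed at `inst/cli/mhc2pred.R` (subcommands `simulate`, `derive-matrix`,
`predict`, `train`, `reduce`, `evaluate`, `sp-impact`, `consensus`).

## Worked example

```r
library(mhc2pred)

w <- synthetic_world(seed = 42)          # ground-truth matrix + parameters
dataset <- simulate_dataset(w, n = 1000) # affinity table with homolog clusters
panel <- simulate_library_panel(w)       # 180 mixture IC50s
mat <- derive_matrix(panel, allele = w$allele)

predict_peptides(mat, c("ACDEFGHIKLMNPQR", "AYAAAKAAALAAAVA"))
#> # A tibble: 2 × 5
#>   sequence        method      score core_start core_seq
#>   <chr>           <chr>       <dbl>      <int> <chr>
#> 1 ACDEFGHIKLMNPQR comblib   519930.          2 CDEFGHIKL
#> 2 AYAAAKAAALAAAVA comblib 17547041.          4 AAKAAALAA

evaluate_fixed_method(mat, dataset, method = "comblib")
#> # A tibble: 1 × 7
#>   allele     method  variant     n n_binder   auc   rho
#> 1 SYN-A*0101 comblib ALL      1000      595 0.805 0.700

evaluate_cv_method(dataset, baseline_trainer(), k = 5, seed = 42,
                   method = "baseline")
#> # A tibble: 1 × 7
#>   allele     method   variant     n n_binder   auc   rho
#> 1 SYN-A*0101 baseline ALL      1000      595 0.890 0.841

ann <- similarity_reduce(dataset)
c(ALL = nrow(ann), SR = sum(ann$in_sr), SP = sum(ann$in_sp))
#>  ALL   SR   SP
#> 1000  731  550
```

The scores are IC50-like (lower = stronger predicted binding); `core_start`
is the 1-based offset of the best 9-mer core. The `auc` column is the area
under the ROC curve for classifying binders (0.5 = random, 1.0 = perfect),
`rho` the Spearman correlation between predicted scores and measured IC50s.
The similarity reduction keeps 731 of 1000 peptides (one representative per
homolog cluster); 550 peptides have no similar partner at all (SP).

## Acceptance script

`scripts/acceptance.R` recomputes the package's numeric acceptance targets
from scratch — the ROC implementation's AUC for an i.i.d. random predictor on
a large balanced label set and for a perfectly separating oracle predictor —
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 42 --out results/acceptance.json
```

## Scope

Internals of external predictors (NN-align, SMM-align, ARB, PROPRED/TEPITOPE)
are out of scope; the harness accepts any predictor through the
`predict_many()` interface, and the built-in trainable matrix predictor
exists so the cross-validation machinery can be exercised end to end.
See `vignettes/mhc2pred-methods.Rmd` for the modelling choices, synthetic-data
assumptions and known limitations.
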