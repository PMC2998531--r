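---
title: "Models and methods behind mhc2pred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mhc2pred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2pred)
```

This vignette is the package's own account of the science it implements: the
binding model, the similarity and redundancy-reduction machinery, the
evaluation harness, the consensus combiner, and the synthetic-data generator
the test suite runs against — together with the numerical choices made where
the design was genuinely open.

## The binding model

MHC class II molecules present peptides to CD4+ T cells. Because the binding
groove is open at both ends, a bound peptide (typically 13–17 residues) can
slide, and affinity is dominated by whichever nine consecutive residues sit
in the groove — the **9-mer core**. The package models a molecule's
specificity as a 9 × 20 matrix $m(p, a) > 0$, one multiplicative weight per
core position $p$ and residue $a$, oriented like an IC50: smaller is
stronger. A core is scored by the product $\prod_p m(p, \mathrm{core}_p)$; a
longer peptide takes the minimum over all its 9-mer windows, and the leftmost
window wins ties (a deterministic convention). Peptides with measured
IC50 < 1000 nM are **binders**; exactly 1000 nM is a non-binder. The cutoff
is the field's convention — it captures roughly 97% of HLA-DR restricted
epitopes — and every derived label in the package uses it.

Scores are products of linear values rather than sums of logs. The two are
rank-equivalent; linear products were fixed so that scores stay loosely
IC50-like in magnitude.

## Deriving matrices from combinatorial library panels

A positional-scanning combinatorial library characterises one molecule with
180 peptide mixtures: 13-mers with alanines at template positions 1, 2, 12
and 13 and an equimolar mix of all 20 residues at the central nine positions,
except one fixed residue. Core position $p$ maps to template position
$p + 2$. Given the 180 mixture IC50s, `derive_matrix()` computes:

1. $G$ — the geometric mean of all 180 IC50s; relative values
   $r(p,a) = \mathrm{IC50}(p,a) / G$. Any global rescaling of the panel
   cancels here, so derivation is scale-invariant.
2. Normalised values $n(p,a) = r(p,a) / \min_a r(p,a)$, so each position's
   optimal residue scores exactly 1.
3. Average relative binding per position,
   $\mathrm{ARB}_p = (\prod_a n(p,a))^{1/20}$, and over the whole panel,
   $\mathrm{ARB}_{\mathrm{all}} = (\prod_{p,a} n(p,a))^{1/180}$.
4. Position weights $w_p = \mathrm{ARB}_{\mathrm{all}} / \mathrm{ARB}_p$ and
   the final matrix $m = n \cdot w_p$ (rows scaled).

The algebraic composition of the weighting step is not fully pinned down by
its verbal description; we apply it multiplicatively to the normalised values
and expose `weighting = TRUE/FALSE`. Because $w_p$ is constant within a
position, every core product changes by the same factor $\prod_p w_p$, so
peptide *rankings* — and hence AUCs — are identical under either setting; the
flag matters only if absolute score magnitudes are interpreted. The full
derivation trace ($G$, $r$, $n$, $\mathrm{ARB}_p$, $w_p$) is attached to the
returned matrix for audit via `derivation_trace()`.

Panels must be positive and complete; values above assay sensitivity should
be censored with `clamp_ic50()` (default ceiling 50 000 nM, floor 0.1 nM,
typical competition-assay limits) before derivation, since geometric means
need finite positive inputs.

## Peptide similarity and the ALL / SR / SP hierarchy

Binding datasets accumulate homologs: overlapping 15-mers tiling an antigen,
single-residue substitution scans of a reference ligand, and near-identical
variants from related proteins. If such peptides straddle a train/test split
they inflate measured performance. Two peptides are **similar** when either

* they share an identical contiguous 9-mer (one shared core register), or
* their best ungapped alignment exceeds 80% identity: over all relative
  offsets with at least one aligned residue, take the maximum count $M$ of
  identical aligned residues; identity is $M / \min(L_1, L_2)$.

The threshold is strict (`> 0.80`): two 15-mers differing at exactly three
positions (identity 0.80) are *not* similar by the identity condition. The
overlap requirement for offsets is a single residue — short overlaps cannot
reach the threshold for realistic lengths anyway.

`similarity_reduce()` builds three nested sets per allele:

* **ALL** — every measurement.
* **SR** — similarity-reduced: the dataset is partitioned into binders and
  non-binders at 1000 nM and each partition is reduced independently by the
  **forward Hobohm-1** algorithm: count each peptide's similar partners
  ($N_\mathrm{similarity}$), sort ascending, then walk the list keeping each
  peptide not similar to anything already kept. The kept set is independent
  (no similar pair), maximal (every discarded peptide is similar to a kept
  one), and — unlike removal in arbitrary order — deterministic. Ties in
  $N_\mathrm{similarity}$ break by lexicographic sequence order (radix,
  locale-independent), then input order. Cross-partition similar pairs may
  survive by construction. `random_reduce()` implements the order-undefined
  comparator: different seeds keep different numbers of peptides, and its
  mean kept-set size does not exceed Hobohm's.
* **SP** — singular peptides, with no similar partner anywhere in ALL.

Two readings of the procedure were possible and are resolved as follows.
$N_\mathrm{similarity}$ used for Hobohm ordering is counted **within the
partition being reduced** (the unit whose internal redundancy is removed);
`scope = "dataset"` switches to counting across the allele's full set. SP is
extracted **globally over ALL** rather than per partition, matching the
set-diagram reading of the hierarchy; with either scope choice SP ⊆ SR ⊆ ALL
holds, which the suite asserts.

The all-pairs similarity kernel is compiled (Rcpp); the test suite pins it to
a naive R brute-force oracle on instances of up to 200 peptides.

## The evaluation harness

`make_folds()` assigns peptides to $k$ folds (default 5) by seeded shuffle
plus round-robin, so fold sizes differ by at most one; the assignment object
is reusable verbatim across methods so that competing predictors see the same
data separations. Whether folds should be stratified by binder status was
left open in the original design; the default here is unstratified, matching
the plain reading of "five-fold cross validation".

`cross_validate()` trains on $k-1$ folds and predicts the held-out fold, so
each peptide receives exactly one blinded prediction. Training-free methods
(library matrices) are instead evaluated on the entire dataset by
`evaluate_fixed_method()`.

`roc_auc()` sweeps the decision threshold from best to worst score, grouping
tied scores into one step; the trapezoidal area then equals the Mann–Whitney
U statistic with half credit for ties — the tie convention of standard ROC
packages. AUC is invariant under monotone transforms of the scores, and
flipping the orientation flag complements it. `spearman_rho()` is the
standard rank correlation (average ranks on ties), sign-aligned so that a
good predictor approaches +1 regardless of score orientation. Reports quote
AUC and rho to three decimals; undefined rho (constant scores) is reported as
a blank (NA) cell rather than zero, as is an unavailable method for an
allele.

### Does training on homologs hurt prediction of unrelated peptides?

`sp_impact_analysis()` answers with a paired design. For each allele it runs
two cross-validations with the same seed: one on ALL, one on SR. Every SP
peptide then has two blinded predictions — one from training that included
homologs, one from training that excluded them. The per-allele SP-set AUCs
are tabulated as `auc_all`, `auc_sr`, `auc_reduction = auc_all − auc_sr`,
with the training-set shrinkage `n_reduced = n_all − n_sr` and
`frac_reduced = 1 − n_sr/n_all`, and a paired two-tailed t-test is run over
alleles. The SR-trained predictions come from folds drawn on the SR set
itself; SP peptides are extracted from whichever folds they land in. On a
dataset with no homologs SR equals ALL and the AUC difference is exactly
zero — the suite asserts this identity. No sign is asserted on real-style
data: differences of either sign are legitimate outcomes.

## The baseline trainable predictor

The harness needs a method that *learns* from affinity data.
`train_core_matrix()` is a deterministic iterative best-core estimator:

* **E-step** — assign each peptide the lowest-scoring 9-mer window under the
  current matrix (initially the leftmost window).
* **M-step** — refit the matrix from the assigned cores by backfitting the
  additive model in log space: cell $(p, a)$ becomes the geometric mean of
  *residual* ratios — each peptide's IC50 relative to the dataset geometric
  mean after dividing out the current contributions of the other eight core
  positions — smoothed by `pseudocount` virtual observations at the neutral
  ratio 1, cycling over positions for `sweeps` rounds.

Iteration stops when assignments stabilise or after `max_iterations`
(default 50; assignments on near-flat positions can oscillate between
equivalent registers, so the cap matters). The residual step is essential: a
naive M-step that attributes a peptide's whole IC50 ratio to all nine of its
core cells washes the motif out under best-window scanning — on the benchmark
world it leaves cross-validated AUC near 0.73 with core assignments at chance,
whereas the backfitting estimator reaches 0.89 with ~80% of cores placed on
the generative register. Working in log space also avoids under/overflow of
long products. Training is bit-reproducible: no randomness enters (the `seed`
field of `trainer_config()` is provenance only), and a global rescaling of
the training IC50s leaves the fitted matrix unchanged.

The predictor interface is a single generic, `predict_many(model, peptides)`:
one row per peptide in input order, `NA` score plus a `note` for per-record
failures (e.g. peptides shorter than 9 residues) rather than a global error.
Anything implementing it — library matrices, trained matrices, external
methods — plugs into `cross_validate()`, the evaluation reports and the
consensus.

## Median-rank consensus

Raw scores of different methods are not commensurable, so methods are
combined on the rank scale. `percentile_rank()` ranks each peptide within the
evaluated set after orientation (1 = best, average ranks on ties) and divides
by $n$; `median_rank_consensus()` scores each peptide by the median of its
per-method percentile ranks (mean of the central pair for even counts). The
consensus is invariant to monotone rescaling of any member and to method
order, and a consensus of copies of one method reproduces that method's
ranking exactly. Ranks are computed within the evaluated peptide set (the
same set over which AUC is computed), not against an external background —
a dialect choice that matters when comparing absolute consensus scores across
datasets.

`leave_one_out_consensus()` quantifies each member's contribution by removing
it and re-scoring; `subset_consensus()` restricts the consensus to a primary
method list with ordered fallbacks substituted per allele where a primary is
unavailable (the "best-3" pattern). Methods unavailable for an allele are
excluded, not imputed.

## The synthetic world

`synthetic_world()` fixes a ground truth from a master seed so that every
pipeline stage can be tested offline:

* **Truth matrix** — anchor positions (default 1, 4, 6, 9, the classic DR
  motif anchors) draw lognormal weights with log-SD `strength` (default 1,
  natural log); non-anchors are near-flat (log-SD `strength/20`); each row is
  scaled so its optimum is 1.
* **Affinity data** — `simulate_dataset()` mixes four generators (defaults:
  55% unrelated random 15-mers, 25% overlapping tiles of a random source
  protein with step 5, 10% single-substitution scan of a reference ligand,
  10% 1–2-substitution variants of a second reference), mirroring how real
  per-allele datasets combine unrelated screens with epitope-mapping scans
  and analog panels. Measured affinity is
  $\mathrm{IC50} = \mathrm{scale} \times \mathrm{bestcore} \times
  10^{\mathcal{N}(0, \sigma)}$, censored to `clamp` (0.1–50 000 nM). The
  defaults — scale 5 nM, $\sigma = 0.3$ log10 units — put a noise-free
  optimal-core peptide at strong-binder affinity and yield binder fractions
  (~0.6 at seed 42) within the 0.27–0.70 range observed across real
  per-allele datasets; $\sigma = 0.3$ is a realistic between-assay
  reproducibility figure.
* **Library panels** — `simulate_library_panel()` sets the $(p,a)$ mixture
  IC50 proportional to the truth entry times the same lognormal noise, at a
  mixture-level scale of 100 nM (derivation is scale-invariant).

What the generator deliberately does **not** emulate: real allele-specific
binding motifs (DP/DQ pocket chemistry), peptide length effects and flanking
residue contributions, position correlations beyond the additive model,
systematic assay artefacts, and cross-allele structure. A green test
therefore establishes that the *machinery* is correct — formulas, algorithms,
determinism, blinding — and that parameter recovery behaves as theory says
(e.g. derived matrices converge to the truth as panel noise vanishes), not
that any particular real-world AUC will be achieved. Conversely, the additive
generative model matches the scoring model's assumptions exactly, so
benchmark AUCs (baseline cross-validated 0.89, library matrix 0.805 at the
default world) are upper-bound-flavoured for methods of this class.

## Numerical choices and degenerate inputs

* Boundary values: IC50 = 1000 nM is a non-binder; identity exactly 0.80 is
  not similar; both thresholds strict by definition.
* Ties: leftmost window for core selection; average ranks in AUC, rho and
  percentile ranks; Hobohm ties by lexicographic then input order.
* Coordinates: 0-based half-open internally, 1-based closed in all
  user-facing tables (`core_start`, positions 1–9).
* Duplicated sequences within an allele keep the first occurrence (logged);
  replicate-merging policy was unspecified upstream, and first-wins is
  order-stable.
* Residues outside the 20-letter alphabet are an error by default
  (`strict = TRUE`), or dropped with a warning in lenient mode — matrices are
  defined over exactly 20 residues.
* Matrix files store linear values at 15 significant digits; round-trips are
  exact to at least 12 significant digits.
* Geometric means and products are computed in log space throughout.
* AUC requires both classes; Spearman requires non-constant vectors and at
  least 3 pairs; report cells are NA when a statistic is undefined.

## Known limitations

* The baseline trainer fits a single additive 9-mer core model — no flanking
  residues, no length terms, no pan-allele sharing; it exists to exercise the
  harness, not to compete with modern predictors.
* `random_reduce()` implements one concrete order-undefined removal rule
  (shuffled pair scan, later member removed); it demonstrates instability,
  not any particular published implementation.
* Similarity is exact-match based (shared 9-mer / ungapped identity); no
  substitution-matrix or gapped similarity.
* The synthetic benchmark shares its functional form with the predictors
  under test (see above), so synthetic AUCs must not be read as forecasts of
  performance on measured data.
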