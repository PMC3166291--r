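---
title: "Methods: structure-informed prediction of temperature-sensitive mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-informed prediction of temperature-sensitive mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmut)
```

## The problem

Temperature-sensitive (ts) alleles — mutations that leave a protein
functional at a permissive temperature but inactivate it at a restrictive
one — are the workhorse of essential-gene genetics in yeast, worm and fly.
They are rare: random mutagenesis followed by screening finds them at great
cost. tsmut implements a rational-design alternative: it assumes the common
mechanism behind ts behaviour is *intermediate* destabilization of the
folded state — enough to unfold the protein at elevated temperature, not
enough to kill it at the permissive one — and searches for substitutions in
that destabilization window.

The pipeline scores each candidate substitution at a buried site by how the
mutation perturbs an *ensemble* of structure-relaxation runs. Each relax run
searches for a low-energy accommodation of the (mutated) structure and
reports a vector of score terms — energy components, repack-trajectory
summaries, and structural-similarity measures against the native structure.
Fifty runs per structure give, per score term, an empirical distribution for
the wild type and one for each mutation. A classifier trained on known ts
and non-ts mutations then maps distribution-comparison features, plus
sequence and structure context, to a calibrated ts confidence.

Running the structure-relaxation engine itself is out of scope: tsmut
consumes its score files (or synthetic stand-ins from the bundled
generator), which is what makes the pipeline testable end to end on a
laptop.

## The quartile-to-percentile statistic

Proteins differ wildly in their baseline energies, so raw score differences
between mutant and wild type are not comparable across proteins. The core
statistic is therefore rank-based. For one score term with mutant-ensemble
values $S$ (n = 50 by default):

1. Sort $S$ ascending and take the **nearest-rank quartiles**: the elements
   at 1-based positions $\lceil 0.25 n \rceil$, $\lceil 0.5 n \rceil$,
   $\lceil 0.75 n \rceil$. Nearest-rank is used because fractional positions
   (e.g. 12.5 at $n = 50$) are otherwise ambiguous; the quartiles are then
   always observed values.
2. Locate each quartile as a **percentile within the wild-type ensemble** of
   the same term. The sorted wild-type values receive plotting positions
   $(i - 0.5)/n$; percentiles are linearly interpolated between them,
   extrapolated beyond the extremes with the adjacent segment's slope, and
   clamped to $[0, 1]$. Tied reference values share the mean of their
   plotting positions, giving mid-range behaviour for discrete terms.

This yields three features per term (`omegaQ1`, `omegaQ2`, `omegaQ3`, ...),
93 features over the 31 standard terms, each in $[0, 1]$. An undisturbed
term maps near (0.25, 0.50, 0.75); a location shift pushes all three toward
an extreme; spread inflation pushes Q1 and Q3 apart. Clamping is essential:
a strongly destabilized mutant's quartiles frequently fall outside the
wild-type range entirely.

The interpolate-then-clamp convention (rather than a pure "fraction ≤ x"
count) was chosen because it is continuous in its input, self-maps a
distribution onto (0.25, 0.5, 0.75) to within $1/(2n)$, and is invariant
under any strictly increasing rescaling applied to both ensembles — the
properties the test suite asserts.

## Candidate enumeration

Substitutions are proposed only at **buried** sites — relative side-chain
solvent accessibility at or below 10% — because destabilization there
perturbs the whole fold rather than one surface interaction. The comparison
is inclusive of the cutoff (a documented flag switches to strict), and the
cutoff is expressed in percent on the command line, as a fraction
internally. Accessibility is consumed as an input table; the package does
not compute it. At each selected site all 19 non-native substitutions are
enumerated, so a protein with $k$ qualifying sites yields a manifest of
$19k + 1$ relax jobs (one per mutation plus the wild type).

## Additional features

- **Category change** (`aminochange`, `aminochange2`): 0 if the residue is
  unchanged, 1 for a substitution within the same chemical category, 2 for a
  category change. Two partitions of the 20 amino acids are shipped (four
  categories: nonpolar / polar / charged / special; seven: small nonpolar /
  large hydrophobic / polar / positive / negative / glycine / proline). The
  memberships are configuration data, not code, and can be overridden.
- **PSSM features**: half-bit integer log-odds and observed percentage of
  the native and substituted residue at the position, their differences,
  and the position information content, read from a PSI-BLAST ASCII PSSM
  exactly as printed (no rescaling). The parser takes the amino-acid column
  order from the file header rather than assuming it.
- **Structure features**: accessibility in percent (`ACCP`) and one-hot
  secondary-structure indicators (`ss_H`, `ss_S`, `ss_L`).

## Redundancy pruning

Features from one score term are kept or removed as a Q1–Q3 trio, since
they are mechanically coupled. The shipped plan
(`default_pruning_plan()`) removes six term trios — `fa_atr`, `fa_sol`,
`fa_intra_rep` (near-duplicates of the kept `fa_dun` group), `maxsub`
(duplicate of `gdtmm7_4`), `rms` (duplicate of `gdtmm2_2`), and `irms`
(always zero) — plus seven individual features: the `ss_*` indicators
(which degrade performance), the `freq_*` features (duplicates of their
`pssm_*` partners), and `aminochange` (keeping the seven-category
`aminochange2`; a flag swaps the choice). That is 25 of the 106 features,
leaving 81. The plan is data, not code, so alternative reconstructions are
a configuration change. `correlated_pairs()` (absolute Pearson correlation,
default threshold 0.9) supports re-deriving such plans; a rank correlation
was not used because the quartile features are already rank-scaled.

## Classifiers

Soft-margin SVMs with linear and RBF kernels (fitted via libSVM through
e1071), plus an "SVM-seq" view that retains only sequence-derived features.
The decision function is the usual kernel expansion
$f(x) = \sum_i \alpha_i y_i K(x_i, x) + b$, evaluated by the package
directly from the stored support vectors so that persisted models re-score
deterministically; for linear kernels the explicit weight vector
$w = \sum_i \alpha_i y_i x_i$ is exposed and drives feature-importance
ranking.

Numerical choices, each configurable:

- **Scaling**: min-max to $[0, 1]$ fitted on training data only. The
  quartile features already live there; min-max keeps the remaining
  features commensurate without distorting their bounded scales.
  Zero-range features map to 0.
- **Calibration**: confidences come from a Platt-style sigmoid
  $\sigma(A f(x))$ with the intercept pinned at zero, fitted on
  training-set margins by one-dimensional likelihood optimisation with
  Platt's smoothed targets. The zero intercept makes confidence > 0.5
  exactly equivalent to a positive margin, i.e. to the predicted ts label;
  a fold-fitted two-parameter sigmoid would break that equivalence and
  (in its usual randomised-CV form) determinism.
- **Class weights**: none by default for the 75/130 imbalance.
- **Ranking**: descending confidence, ties broken by mutation id, so
  output files are byte-reproducible. The ranked-list format is
  `rank conf id` with three-decimal confidences and ids like
  `YBR109C-F140_GLY_Scer`.

## Evaluation harness

- `kfold_splits()`: stratified folds (samples shuffled within class and
  dealt round-robin), sizes differing by at most one, deterministic per
  seed. Stratification keeps ts examples in every fold of a 75/130 set.
- `repeated_cv()`: k-fold CV repeated with incremented seeds; metrics are
  pooled within each repetition and summarised as mean and variance across
  repetitions.
- `grid_search()`: exhaustive sweep of a log2-spaced lattice, default
  $C \in 2^{-5}..2^{15}$, $\gamma \in 2^{-15}..2^{3}$ at steps of $2^2$
  (classic libSVM-era ranges), scored by ts-class precision (the quantity
  the design task cares about — how many proposed mutants are real);
  ties break toward the least complex model (smaller C, then smaller
  gamma).
- `leaveout_cv()`: five disjoint stratified 80/20 splits; the grid search
  runs on each 80% only, the winner retrains on that 80%, and metrics pool
  the five untouched 20% sets — so no sample is ever scored by a model
  that saw it or whose hyperparameters it influenced. Final
  hyperparameters are the component-wise medians of the five selected
  points in log2 space.

Metrics: ts precision TP/(TP+FP); AUROC as the tie-aware normalized
Mann–Whitney statistic; PR curve integrated in average-precision form; and
the point-biserial correlation
$(M_1 - M_0)/s_n \cdot \sqrt{pq}$, which is identically the Pearson
correlation of confidence with the 0/1 outcome (asserted to 1e-12 in the
tests).

## The synthetic-data generator

The generator exists so the entire pipeline — file dialects, features,
training, nested CV — runs and is tested without any external
structure-modelling, alignment, or curated data.

An `ensemble_model()` fixes per-term wild-type locations and spreads
(order-of-magnitude realistic for a small globular protein; the rank-based
statistic is indifferent to the actual values) and the ensemble size of 50.
A `mutation_effect()` plants a destabilization of severity $\delta$ (in
wild-type-spread units) on five designated sensitive terms — the overall
score, the repack-trajectory variability, the backbone-statistics term and
two mid-threshold similarity fractions — as a location shift of
$\delta \sigma_t$ with spread inflation $\kappa$. The planted label rule
operationalizes the intermediate-destabilization premise directly: a sample
is ts exactly when $\delta \in [1.5, 4]$; below the band the mutation is
tolerated, above it it is outright loss of function (drawn up to 3 spread
units above the band, half of the non-ts mass on each side).

The default severity–spread coupling is $\kappa = 1 + 0.4\delta^2$.
The quadratic form is deliberate: the percentile map clamps once a shifted
quartile leaves the wild-type range (at roughly $\delta > 2.5$), so a pure
location effect makes every severe mutation look identical and the upper
band edge unlearnable. Physically, ensembles of severely destabilized
structures fail to settle and wander far beyond the wild-type range, so
spread grows faster than location; quantitatively, the quadratic keeps
within-band quartiles inside the wild-type range while pushing
loss-of-function Q1 values back below it, encoding severity in the feature
vector on both sides of the band.

`generate_training_set()` draws 75 ts / 130 non-ts samples (the shape of a
realistic curated mutation collection) and runs the *real* feature pipeline
on generated ensembles, synthetic PSSMs and accessibility tables. The
sequence and structure features therefore carry no planted signal — they
are honest nuisance dimensions for the classifier.

What the generator does **not** emulate: correlations between score terms
(real energy components co-vary strongly; the shipped pruning plan exists
precisely because of that), heavy-tailed or multimodal relax score
distributions, position-dependent effect sizes, sequence–structure coupling
(real conservation predicts destabilization; synthetic PSSMs are
independent of the planted label), and any actual physics. Passing tests
therefore demonstrate that the machinery is correct and that a planted
intermediate-destabilization band is recoverable through the full feature
pipeline — not that the method attains any particular accuracy on real
proteins.

## Interpretive linear probe

For feature-importance readout the package trains a linear SVM and ranks
features by |weight|. This probe uses stronger regularization
($C = 0.25$) than the predictive models: at 205 samples and ~81 features a
loosely regularized linear fit distributes weight onto chance correlations
in the nuisance features, whereas the regularized probe concentrates it on
the planted sensitive terms. On the synthetic conditions the designated
terms' quartile features reliably dominate the top of the ranking.

## Problem sizes and determinism

The test suite and the acceptance script work at the study scale the
package targets: 50-decoy ensembles, 205-sample training sets, five
leave-out splits, and a reduced 5 × 5 hyperparameter lattice with a
single inner repetition for the nested-CV demonstrations (the full
default lattice is 11 × 10 with multiple repetitions). Every stochastic
step — generation, fold assignment, grid evaluation — descends from a
single integer seed, and the RNG state of the caller is always restored,
so all reported quantities are bit-reproducible.

## Known limitations

- Accessibility, secondary structure and PSSMs are inputs; generating them
  (surface-area computation, DSSP-style assignment, PSI-BLAST) is the
  user's responsibility.
- The burial cutoff treats accessibility as exact; no uncertainty model.
- Calibration is a single-slope sigmoid fitted on training margins;
  confidences are monotone in the margin but can be over-confident for
  small training sets.
- The 5 × leave-out precision estimate is conservative but still shares the
  training distribution; prospective performance on novel proteins is
  unknowable from the synthetic conditions by construction.
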