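# tsmut

Structure-informed prediction of temperature-sensitive (ts) point
mutations.

Temperature-sensitive alleles — substitutions that leave a protein
functional at a permissive temperature and inactivate it at a restrictive
one — are the classic tool for studying essential genes in yeast, worm and
fly, and they are painful to find by screening. tsmut ranks candidate
substitutions at buried sites by how likely they are to land in the
*intermediate destabilization window* that produces ts behaviour: too
little destabilization is tolerated, too much is outright loss of
function, and ts lives in between.

The package is aimed at structural-bioinformatics users who can run a
structure-relaxation engine (to produce per-mutation "SCORE:" ensembles)
and want the downstream statistics, classifiers, evaluation harness and
ranked output handled for them — plus a synthetic-data generator that
stands in for every external input, so the whole pipeline runs and is
tested offline.

## The method

For each candidate mutation, an ensemble of ~50 relaxation runs gives an
empirical distribution of every score term. The core statistic compares a
mutant ensemble to the wild-type ensemble per term, free of any
distributional assumption:

- quartiles Q1–Q3 of the mutant values (nearest rank:
  element at position ⌈p·n⌉ of the ascending sort, p = 0.25, 0.5, 0.75);
- each quartile mapped to its percentile within the wild-type values of
  the same term (interpolated empirical CDF with plotting positions
  (i − 0.5)/n, linearly extrapolated, clamped to [0, 1]).

This yields 93 features from 31 score terms (`omegaQ1`, `p_aa_ppQ3`, ...),
joined by sequence features (amino-acid category change, PSI-BLAST PSSM
log-odds/frequencies, information content) and structure features (percent
accessibility, secondary-structure indicators), pruned for redundancy to
the final training set.

Classification is by soft-margin SVM. Labels follow the sign of the
decision function

    f(x) = Σᵢ αᵢ yᵢ K(xᵢ, x) + b

with linear (`SVM-LIN`, K(u, v) = u·v, equivalently f(x) = w·x + b) and
RBF (`SVM-RBF`) kernels, plus a sequence-only `SVM-seq` variant.
Confidences come from a zero-intercept Platt sigmoid on the margin, so
confidence > 0.5 is exactly the ts label, and candidates are ranked by
confidence. Evaluation uses stratified 10×10-fold CV and a nested
5× leave-out scheme: hyperparameters are grid-searched on each 80% split
only and all metrics (ts precision, AUROC, AUPR, point-biserial
correlation of confidence with correctness) pool the untouched 20% sets.

## Worked example

A synthetic toy workspace stands in for relaxation output
(`generate_toy_workspace()` writes score files, accessibility table, PSSM
and a labelled training matrix), after which the four pipeline stages run
as in production:

```r
library(tsmut)

dir <- "demo"
generate_toy_workspace(dir, protein = "TOY1", n_res = 12, n_buried = 2, seed = 4)
config <- run_config("TOY1", dir = dir, seed = 4)
cmd_generate(config)   # manifest: 2 buried sites -> 39 jobs (19*2 + WT)
cmd_train(config)      # fits SVM-LIN + SVM-RBF on training.tsv
cmd_predict(config)    # writes TOY1-svmlin.txt / TOY1-svmrbf.txt
readLines(file.path(dir, "TOY1-svmrbf.txt"))[1:6]
```

```
rank conf id
1  0.959 TOY1-M2_HIS_Scer
2  0.868 TOY1-S6_LYS_Scer
3  0.810 TOY1-S6_TYR_Scer
4  0.803 TOY1-S6_ILE_Scer
5  0.754 TOY1-S6_LEU_Scer
```

Each line is the rank, the calibrated ts confidence, and the mutation id
(protein, native residue + position, substituted residue as a three-letter
code, species): the "top 5" list one would take to the bench. The same
functions compose programmatically, e.g. recovery of the planted
destabilization band from fresh synthetic data:

```r
train <- apply_pruning(generate_training_set(seed = 1))   # 75 ts / 130 non-ts
test  <- apply_pruning(generate_training_set(seed = 5001))
rbf   <- train_svm(train, kernel = "rbf", C = 8)
auroc(test$class, predict_confidence(rbf, test))
#> 0.892

lin <- train_svm(train, kernel = "linear", C = 0.25)
head(feature_weights(lin), 5)
#> # A tibble: 5 × 2
#>   feature              weight
#>   <chr>                 <dbl>
#> 1 scoreQ1               1.03
#> 2 gdtmm7_4Q1            0.887
#> 3 p_aa_ppQ2             0.869
#> 4 scoreQ2               0.859
#> 5 Repack_stdev_scoreQ1  0.761
```

The held-out AUROC shows the planted intermediate-destabilization rule is
recovered through the full feature pipeline, and the top linear weights
fall on the quartile features of the designated sensitive score terms.

A thin command-line front end wraps the same stages
(`inst/cli/tsmut generate|predict|train|evaluate|fixtures`).

## Documentation

The methods vignette (`vignettes/tsmut-methods.Rmd`) documents the model
and its assumptions, every numerical convention (quartile and percentile
definitions, tie handling, scaling, calibration), the evaluation harness,
what the synthetic generator does and does not emulate, and known
limitations.
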