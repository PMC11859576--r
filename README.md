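# imbga

Binary classification of heavily imbalanced tabular medical data, built
around three pieces that are usually bolted together ad hoc:

1. **AMOM-DUMS hybrid resampling** — the minority class (label `0`,
   e.g. the rare clinical outcome) is grown by interpolating between a
   sample and one of its *m* nearest minority neighbours,
   `u_new = u_i + s (u_ij − u_i)`, `s ~ U(0,1)`; the interpolation noise
   is then cleaned by iteratively removing the majority member of every
   *Tomek link* (a cross-class mutual-nearest-neighbour pair) until none
   remains.
2. **Improved F-score feature selection** — features are ranked by the
   discriminability ratio
   `F'_i = [(Ū⁺−Ū)² + (Ū⁻−Ū)²] / [(1/(n⁺−1)) Σ (U⁺−Ū⁺)²]`,
   the imbalance-aware variant of the Fisher-style F-score that drops
   the noisy minority-class variance from the denominator; a
   cross-validated wrapper then picks the best subset size.
3. **A GA-optimized stacked ensemble** — a two-layer stack whose first
   layer is a subset of 10 heterogeneous classifiers (SVM, AdaBoost,
   random forest, bagging, two gradient-boosting variants, naive Bayes,
   Gaussian process, logistic regression, k-NN) encoded as a length-10
   bitstring chromosome; a genetic algorithm (roulette selection
   `P_i = fit_i / Σ fit_j`, multi-point crossover, bit-flip mutation,
   elitism) searches the 1,023 subsets with cross-validated AUC as
   fitness, and a balanced ridge-logistic meta-learner
   `P(v=1|u) = 1/(1+e^(−w'ᵀu))` fuses the selected members'
   out-of-fold probabilities.

It is aimed at methods work on imbalanced clinical prediction: every
stage is a plain exported function on a shared `imb_dataset` container,
cross-validation is leak-free under oversampling (resampling happens
inside training folds; held-out rows are always real), and a synthetic
generator reproduces the class-count shapes of the motivating perinatal
cohorts (UR 4.324 / 23.349 / 16.049 and a severe 42 : 2,136 = 50.86
scenario with 25 features) so everything is testable without patient
data.

## Worked example

```r
library(imbga)

d <- scenario_generate(scenario_preset("tableA", rng_seed = 1))
d
#> <imb_dataset> 2087 samples x 20 features
#>   minority (0): 392   majority (1): 1695   UR: 4.324

res <- run_pipeline(dataset = d, seed = 1,
                    ga = ga_config(population_size = 12, generations = 8),
                    cv_folds = 3, max_dim = 10)
res
#> <imb_pipeline_result> seed 1
#>   UR 4.324 -> 1.000 after resampling
#>   features: inf1, inf2, red6, inf4, inf3, inf5, red1, red4, red2, red7
#>   chromosome: 1000101010
#>   test: recall 0.797  F 0.591  AUC 0.866
#>   SVM baseline (raw data): recall 0.102  F 0.180  AUC 0.863
#>   SVM with pipeline preprocessing: recall 0.822  F 0.602  AUC 0.874
```

Reading the output: resampling balanced the training classes
(UR 4.324 → 1.000); the wrapper kept 10 features, led by the five
planted informative ones; the GA selected a four-member first layer
(chromosome bit k retains pool member k — here SVM, GBDT, naive Bayes,
logistic); on the untouched test split the pipeline detects 79.7% of
the rare-class cases where the raw-data SVM finds 10.2%, at essentially
the same ranking quality (AUC). The second SVM line is a diagnostic:
a single SVM handed the *same* resampled, feature-selected data — on
clean Gaussian scenarios it matches the ensemble, a limitation
discussed in the methods vignette.

Individual stages are available directly: `compute_ur()`,
`minmax_normalize()`, `amom_oversample()`, `dums_clean()`,
`amom_dums()`, `fscore_standard()` / `fscore_improved()` /
`rank_features()`, `wrapper_select()`, `pool_oof_matrix()` /
`fit_stack()` / `predict()`, `ga_optimize()` /
`exhaustive_stack_search()`, `grid_search()`,
`classification_report()`.

## Command line

A thin CLI over the same functions ships in `inst/cli/imbga.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/imbga.R", package = "imbga"))')
Rscript $CLI simulate --preset pih1 --seed 42 --out synthetic.csv
Rscript $CLI sample   --in synthetic.csv --out sampled.csv --m 5 --seed 42 \
                      --report sampling.json
Rscript $CLI select   --in sampled.csv --out scores.json --max-dim 20
Rscript $CLI pipeline --preset pih1 --seed 42 --report report.json
```

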