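# eegnetage

Graph-theoretic analysis and classification of aging EEG functional
networks.

## What it does

Functional brain networks estimated from EEG change with healthy aging:
network efficiency, clustering and connection strength tend to be lower in
elderly than in middle-aged adults, at rest and during working-memory
tasks. `eegnetage` is an R implementation of the full analysis chain used
to quantify and classify those differences from low-density (8-electrode)
EEG, for researchers studying cognitive aging with portable EEG systems:

- **Preprocessing**: zero-phase Butterworth band-pass (0.5–45 Hz), 50 Hz
  notch, segmentation into 20-s epochs.
- **Network construction**: per-epoch Pearson correlation
  `r = cov(x, y) / sqrt(var(x) var(y))` between electrode pairs, then
  sparsity thresholding to a fixed edge density (top
  `round(density * N(N-1)/2)` edges by |r|), so all subjects' networks are
  compared at equal wiring cost.
- **Seven graph measures** per network, weighted (edge length 1/w) or
  binary: local efficiency, clustering coefficient, global efficiency,
  characteristic path length, node strength, node betweenness centrality,
  degree assortativity.
- **Feature vectors** of 7 measures × 8 electrodes × 9 epochs = 504 values
  per subject per state.
- **Group statistics**: Wilcoxon rank-sum per measure and state (α = 0.05).
- **Classification** of middle-aged-like vs elderly-like subjects with KNN
  (Euclidean, K ∈ {1,3,5}), SVM with the Pearson VII universal kernel, and
  random forest, under stratified 10-fold cross-validation, scored by
  accuracy, sensitivity, specificity, Cohen's kappa, precision, F-score
  and AUC.

Because a suitable public cohort is not available, the package ships a
synthetic EEG generator (`simulate_cohort()`) that mixes band-limited
sources through a channel-coupling matrix whose strength differs between
groups, so every stage of the pipeline is testable end to end against
planted, known effects. See the methods vignette
(`vignettes/eeg-network-aging.Rmd`) for the model and all design choices.

## Worked example

```r
library(eegnetage)

cfg <- cohort_config(n_per_group = 10, seed = 7)   # 10 + 10 subjects, 3 states
cohort <- simulate_cohort(cfg)
fit <- eegnet_fit(cohort)                          # density 0.3, weighted, 9 x 20 s epochs
fit
#> <eegnet_fit>
#>   20 subjects x 3 state(s); 504 features/subject/state
#>   networks: density 0.3 (weighted), 9 epochs of 20 s

summary(fit)   # Wilcoxon rank-sum tests per measure and state (excerpt)
#> Group comparison (Wilcoxon rank-sum, direction < 0 = elderly lower):
#>         metric       state statistic  p_value direction significant
#>        loc_eff eyes_closed     100.0 0.000183        -1        TRUE
#>     clustering eyes_closed      91.0 0.002190        -1        TRUE
#>       glob_eff eyes_closed      90.0 0.002830        -1        TRUE
#>      char_path eyes_closed       0.0 0.000183         1        TRUE
#>       strength eyes_closed     100.0 0.000183        -1        TRUE
#>    betweenness eyes_closed       3.5 0.000499         1        TRUE
#>  assortativity eyes_closed      38.0 0.385000         1       FALSE
#>  ...

classify_cohort(fit, "eyes_closed", model = list(classifier = "knn", k = 3),
                folds = 10, seed = 7)
#> <classification_report> knn, 10-fold CV (seed 7)
#>   accuracy 80.00% | sens 0.800 | spec 0.800 | kappa 0.600 | F 0.800 | precision 0.800 | AUC 0.880
#>   confusion: TP 8  FN 2  FP 2  TN 8 (positive = elderly)
```

Reading the output: efficiency, clustering and strength are significantly
lower in the elderly-like group (direction −1) and characteristic path
length significantly higher — the planted aging pattern — while
assortativity does not separate at this reduced cohort size. A
3-nearest-neighbour classifier reaches 80% cross-validated accuracy
(kappa 0.60) on 10 + 10 subjects; at the full default size (20 + 20, as run
by the acceptance script) KNN accuracy is 92-98% per state. With
`coupling_delta = 0` (no planted effect) the same pipeline rejects at the
nominal 5% rate and classifies at chance.

A command-line wrapper is in `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --state ec --classifier knn --k 3 \
    --density 0.3 --seed 42 --out results/
```

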