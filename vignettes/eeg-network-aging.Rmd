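---
title: "Graph-theoretic analysis of aging EEG functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of aging EEG functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegnetage)
```

## The analysis

Healthy aging reorganises the brain's functional networks: compared with
middle-aged adults, elderly adults tend to show lower functional-network
efficiency, clustering and connection strength in resting-state and
working-memory EEG. `eegnetage` implements the full analysis chain used to
quantify and classify such differences from low-density (8-electrode) EEG:

1. **Preprocessing** — zero-phase Butterworth band-pass (0.5–45 Hz) and 50 Hz
   notch filtering, edge-transient trimming, segmentation into 20-s epochs.
2. **Network construction** — per-epoch Pearson correlation between all
   electrode pairs; sparsity thresholding retains the strongest
   `round(density * N(N-1)/2)` edges so every network is compared at equal
   wiring cost (default density 0.3).
3. **Graph measures** — local efficiency, clustering coefficient, global
   efficiency, characteristic path length, node strength, node betweenness
   centrality and degree assortativity, in weighted (default) or binary mode.
4. **Group statistics** — two-sided Wilcoxon rank-sum tests per measure and
   state at α = 0.05, on per-subject epoch means, uncorrected.
5. **Classification** — middle-aged-like vs elderly-like with KNN, an SVM
   using the Pearson VII universal kernel, and random forest, under
   stratified 10-fold cross-validation scored by accuracy, sensitivity,
   specificity, Cohen's kappa, precision, F-score and AUC.

Because no public recording accompanies the design this package targets, a
synthetic-cohort generator is a first-class component: every downstream
stage is exercised, end to end, on data whose group structure is planted and
therefore known.

## The connectivity model

For electrodes $x, y$ with epoch samples $x_t, y_t$, the edge weight is the
Pearson correlation

$$ r_{x,y} = \frac{\operatorname{cov}(x,y)}
   {\sqrt{\operatorname{var}(x)\operatorname{var}(y)}}. $$

Negative correlations are ranked and weighted by $|r|$: thresholding needs a
single ordering and the metric formulas assume nonnegative weights. The
retained-edge count is exact by construction, ties at the cutoff break by
lexicographic electrode-pair order, so thresholding is deterministic and
edge sets are nested across densities.

## The seven measures

Weighted shortest paths use edge length $1/w$ (a stronger correlation is a
shorter path). With $L_{ij}$ the shortest-path length and $N$ nodes:

* **Global efficiency** $\mathrm{GlobE} = \frac{1}{N(N-1)}\sum_{i \ne j}
  1/L_{ij}$, with $1/\infty = 0$; the nodal value $e_i$ averages $1/L_{ij}$
  over $j \ne i$.
* **Local efficiency** of node $i$: mean inverse distance between $i$'s
  neighbours inside the neighbourhood subgraph with $i$ removed; nodes of
  degree < 2 score 0, and the network value divides by $N$ regardless, so
  degree-deficient nodes pull the average down rather than vanish from it.
* **Clustering coefficient** of node $h$:
  $\sum_{i,j} a_{ij}a_{ih}a_{jh} / (d_h(d_h-1))$ over the *binary* connection
  pattern, in weighted mode too — the formula is written in terms of the
  adjacency indicator, and we keep that literal (documented asymmetry:
  strength uses weights, clustering uses the pattern).
* **Characteristic path length**: mean distance over reachable ordered pairs
  only, with the unreachable-pair count reported alongside; a disconnected
  network therefore keeps a finite CP while the efficiency measures encode
  the disconnection.
* **Node strength** $S(i) = \sum_j M_{ij}$.
* **Betweenness centrality** $NB(u) = \sum_{\{v,w\}: u \ne v \ne w}
  P_{v,w}(u)/P_{v,w}$ over unordered pairs, unnormalised, with
  shortest-path counts from a Dijkstra sweep whose path-length ties are
  compared at relative tolerance $10^{-10}$.
* **Assortativity**: the edge-wise degree–degree correlation (strengths in
  weighted mode); degree-regular graphs give 0/0 and return NaN.

Every measure is cross-checked in the test suite against independent
brute-force implementations (Floyd–Warshall distances, exhaustive
simple-path enumeration, direct triangle counting) on *all* connected graphs
with up to 5 nodes, and against closed forms on complete graphs, paths,
stars and cycles.

## Feature layout

Each subject/state contributes a vector of 7 measures × N electrodes ×
n_epochs values (504 at the defaults). Three measures are network-level as
usually defined; to keep the per-electrode layout well defined in every slot
the nodal analogues are used — nodal efficiency for the global-efficiency
slot, nodal mean distance for the path-length slot — and assortativity is
broadcast to all electrodes. A `layout = "broadcast"` switch instead
repeats the network scalars across the slots. Undefined values (NaN
assortativity on degree-regular networks, path lengths of isolated nodes)
are imputed as 0 with a warning so the classifier input is always complete.

## The synthetic cohort

`simulate_cohort()` generates two groups of `n_per_group` subjects (default
20 + 20) in three states: eyes open (300 s), eyes closed (300 s) and a
visual working-memory task (120 s, matching a 4 × 30 s task timeline), at
250 Hz on 8 electrodes (FP1, FP2, C3, C4, P7, P8, O1, O2).

Each channel is a linear instantaneous mixture of independent band-limited
sources — not a biophysical model, a statistical stand-in that induces
exactly the Pearson structure the pipeline consumes:

* **Sources** are nonstationary narrowband processes: filtered noise in a
  1-Hz-wide alpha subband (centre drawn in 9–12 Hz) plus a beta subband
  (16–28 Hz, weight 0.5) plus weak 0.5–45 Hz background (weight 0.2). The
  narrow bands keep the effective number of independent samples per 20-s
  epoch modest, so epoch-level connectivity estimates fluctuate the way
  real EEG connectivity does, instead of repeating a frozen oscillation.
* **Coupling**: a subject's channel correlation matrix is
  `coupling × profile + jitter`, projected to the nearest valid correlation
  matrix and applied through its Cholesky factor. The fixed spatial profile
  has strong within-hemisphere coupling (1.4), moderate homologous
  (mirror-electrode) bridges (1.1) and weak diagonal cross-hemisphere
  coupling (0.45), normalised to mean 1 — so the *expected* mean
  off-diagonal coupling equals the group's coupling strength.
* **Groups**: middle-aged-like subjects couple at `coupling_mid` (default
  0.6), elderly-like at `coupling_mid − coupling_delta` (default 0.3).
  Per-subject coupling jitter (SD 0.05) and edge-wise structural jitter
  (SD 0.08) overlap the group distributions so rank tests are
  non-degenerate.
* **Sensor noise**: additive white noise (SD 0.4 against unit-variance
  channels).

Why this produces the reported aging pattern: weighted efficiency and
strength scale directly with coupling, so they are lower in the elderly-like
group by construction. The clustering contrast is subtler — at fixed density
the binary pattern of a middle-aged-like network recovers the profile's
clustered within-hemisphere pairs almost deterministically, while the
elderly-like group's smaller coupling contrast is comparable to the
epoch-level sampling noise of the correlation estimates, so its thresholded
topology is partially randomised and its clustering coefficient drops.
With `coupling_delta = 0` the two groups are exchangeable and downstream
tests reject at the nominal 5% rate (verified over 100 replicate cohorts).

What the generator does **not** emulate: 1/f spectral shape, ocular/muscle
artifacts (synthetic data are artifact-free, so the FastICA stage used on
real recordings has no counterpart here — `eegnet_fit()` is the hook point
where cleaned recordings enter), event-related dynamics in the
working-memory state, and volume-conduction leakage. Passing tests
demonstrate that the *pipeline* recovers planted effects of realistic size;
they are not evidence about any particular real cohort.

## Seeds and determinism

All randomness descends from integer seeds. Per-recording seeds are a
stable arithmetic hash of (master seed, subject index, group, state), so a
cohort regenerates bit-identically and independently of generation order.
Cross-validation fold assignment, random-forest tree growth, and every test
and script stream likewise derive from explicit seeds; generator functions
restore the caller's RNG state.

## Statistical and classification choices

* Rank-sum tests run on per-subject epoch means (subjects are the
  independent units); a per-epoch option exists. The exact null
  distribution is used when `min(n_a, n_b) <= 8` with no ties, otherwise
  the normal approximation with tie correction. No multiplicity correction
  by default (a Benjamini–Hochberg switch is provided).
* Classification likewise defaults to one instance per subject, so the CV
  unit matches the statistical unit. The epoch-level mode (9 instances per
  subject) is available; there, whole subjects are assigned to folds, since
  splitting a subject's epochs across folds lets the classifier recognise
  the subject rather than the group and inflates accuracy — a leakage worth
  naming because evaluations that pool epochs as instances are common.
* Min–max normalisation is fitted inside each training fold and applied to
  the fold's test data unclipped; constant features map to 0.
* The SVM uses the Pearson VII universal kernel
  $K(x,y) = 1/\left[1 + \left(2\sqrt{2^{1/\omega}-1}\,\lVert x-y\rVert
  /\sigma\right)^2\right]^{\omega}$ with $\omega = \sigma = 1$ (an RBF
  switch exists). Random forests use 100 trees and $\lceil\sqrt p\rceil$
  candidate features per split, seeded. KNN uses Euclidean distance with
  K ∈ {1, 3, 5}; distance ties break by training order and vote ties
  toward the elderly (positive) class.
* AUC comes from pooled out-of-fold scores: positive-vote fraction (KNN),
  oriented decision values (SVM), positive-tree fraction (RF).

## Numerical and degenerate-input conventions

Zero-variance channels abort connectivity with the channel named; densities
yielding zero edges, invalid bands, inconsistent labels and short recordings
raise labelled input errors. The band-pass design order defaults to 3: the
doubled (forward–backward) response of a 2nd-order design still passes about
17% of a 60 Hz tone with the default band, and one extra order brings
stop-band leakage under 10% while leaving in-band amplitudes within 5%.
Epochs tile from the recording start when the duration allows and otherwise
spread uniformly over the feasible offsets (so the 120-s working-memory
recordings yield 9 overlapping 20-s epochs); the first and last 2 s of each
filtered recording are excluded as filter settling.

## Problem sizes used by the checks

The test suite exercises the exhaustive metric oracles on all ~750
connected graphs with ≤ 5 nodes; null-calibration uses 100 replicate
reduced cohorts (10 + 10 subjects, one 68-s state, 3 epochs), and the
planted-effect and classification checks run one full default cohort
(20 + 20 × 3 states). `scripts/acceptance.R` regenerates a full default
cohort from the supplied seed and recomputes feature counts, group
statistics and cross-validated classification from scratch.

## Known limitations

Eight electrodes give 28 possible edges; at density 0.3 a network has 8
edges, so connected topologies can carry at most one cycle and
binary-pattern measures are coarse. The generator's group effect is a
single global coupling factor — it does not produce band-specific or
regionally selective aging effects. CP over reachable pairs only is
optimistic for fragmented networks; read it together with the efficiency
measures. None of the classification accuracies on synthetic cohorts are
estimates of accuracy on recorded EEG.
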