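---
title: "Methods: sliding-window Granger-causality networks and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window Granger-causality networks and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by `tvgc`, the
assumptions it rests on, the choices made where the design was genuinely
open, and what the synthetic validation does and does not establish.

## 1. The estimation pipeline

The pipeline runs in five fixed stages, each a pure function of its inputs,
configuration and seed: session generation (or ingestion), preprocessing,
sliding-window Granger causality (GC), graph metrics, and group statistics.

### 1.1 Pairwise Granger causality

For each ordered channel pair and each sliding window, the package fits an
order-`p` univariate autoregression of the target on its own past and a
bivariate one that adds the source's past, both by ordinary least squares
without intercept, and reports

F(source → target) = ln(RSS_univariate / RSS_bivariate),

the log-ratio of in-sample prediction-error variances. Assumptions: the
windowed series are (locally) stationary, linear, and adequately described
by a finite-order AR model with white innovations. Because the univariate
model is nested in the bivariate one and both are fitted in-sample, every F
is nonnegative up to rounding — an invariant asserted across the entire test
suite at a floor of −1e−10.

The symmetric interaction strength max(F_{Y→X}, F_{X→Y}) is computed and
stored on every GC matrix, but all downstream network analysis uses the
directed matrix: node strength is explicitly split into in- and out-strength.

### 1.2 Aggregation level

GC is estimated **per trial per window** and averaged across trials within a
(subject, band, condition, window) cell. The alternative — concatenating
trials before fitting — would inflate the effective sample but splices
discontinuous segments into one series, violating the AR model at every
joint. Per-trial fitting also keeps each fit inside a 500-sample window,
which comfortably supports the default order 12 (24 coefficients against
488 effective observations for a bivariate fit).

### 1.3 Model-order selection

`select_order()` scores the bivariate fit of every channel pair with
AIC = n·ln(RSS/n) + 2k, where `n` is the post-truncation observation count
(window samples − p) and `k` counts all estimated coefficients of the model
being scored (2p for a bivariate equation). Scores are averaged over the
first five lead trials of the collision condition (plus an optional random
10% subsample of remaining trials), all windows and all pairs; the argmin
wins, ties going to the smaller order. The default search range is 1–15 and
the default fixed order 12; both are configuration fields.

## 2. Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| analysis rate | 500 | Hz | halves data volume; keeps beta band ≪ Nyquist |
| alpha band | 8–13 | Hz | clinical-EEG convention |
| beta band | 13–30 | Hz | clinical-EEG convention |
| epoch span | [−2, +1] | s | event-anticipation window around the hazard midpoint |
| window length / overlap | 1 / 0.5 | s / fraction | 500 samples per window; five windows tiling the epoch |
| AR order `p` | 12 (search 1–15) | lags | supported by 500-sample windows |
| artifact z threshold | 3 | — | conventional feature-z-score cut |
| edge retention | top 5% | — | rendering-oriented sparsification |
| FDR level | 0.05 | — | standard |

Band edges are nowhere forced: any numeric passband is accepted.

## 3. The synthetic generator

### 3.1 What it emulates

`simulate_session()` produces, per subject, a continuous multichannel
recording from a stable vector autoregression whose directed coupling graph
is known, with 40 trials per session, a 50% collision rate, 1 kHz
acquisition, events at trial midpoints, per-trial correctness flags and
log-normal reaction times around 600 ms. A burn-in of 10× the generative
order is discarded so the recorded series is stationary from the first
sample. Innovations are independent Gaussians per channel: the GC framework
models exactly linear-AR signals with white noise, so this is the matched
generative family — deviations from it are a property of real data, not of
the estimator's null.

The two groups differ by construction: the experienced graph is a directed
ring backbone (guaranteeing every channel at least one inbound and one
outbound edge) plus random extra edges; the novice graph reuses those edges
with magnitudes scaled 1.5× and adds 50% more random edges. Because the
novice edge set contains the experienced one, every channel's expected
strength is elevated, which is what makes the "higher novice connectivity in
every intrinsic network" recovery check well-posed. Overlapping feedback
cycles among random extras can make a dense graph explosive, so both groups'
couplings are shrunk by a common factor (preserving the 1.5 ratio) until the
companion spectral radius clears 1 with margin; the effect magnitudes are
therefore free parameters only up to this stability constraint.

The channel atlas assigns contiguous, nearly equal blocks of channels to the
seven intrinsic networks. Real analyses should supply an anatomically
meaningful atlas; the synthetic one only guarantees every network is
populated.

### 3.2 What it does not emulate

No volume conduction, no common reference artifacts, no 1/f background or
realistic EEG spectra beyond AR coloration, no ocular or muscular artifacts
beyond what the screening test plants deliberately, and no source-space
geometry — nodes are channels. Consequently, passing the recovery suite
shows the estimator chain is correct **for its own model class**; it does
not show robustness to mixing or non-stationarity in real recordings.

## 4. Numerical choices

* **QR, never normal equations.** Band-limited signals have severely
  ill-conditioned lag designs (a near-bandlimited process is almost
  perfectly predictable, so the design is almost collinear). All AR fits run
  Householder QR on the design itself; forming the Gram matrix squares the
  condition number and fails outright on filtered data.
* **Rank tolerance 1e−12.** Rank deficiency should trip on genuinely
  duplicated or constant series, not on ill-conditioning; the default 1e−7
  tolerance of R's least-squares routines misfires on narrowband data.
* **Degeneracy guard.** A bivariate residual sum of squares at or below
  1e−20 of the largest target energy aborts the pair: at that level the
  residual is rounding noise and the log-ratio meaningless. On filtered
  data, legitimate residuals sit many orders above this floor.
* **Demeaning.** Each window is mean-subtracted per channel before fitting,
  because the AR models carry no intercept.
* **Indexing.** Sample indices are 0-based and windows half-open
  `[start, end)`, so the five default windows are exactly
  {0–500, 250–750, 500–1000, 750–1250, 1000–1500} at 500 Hz and the event
  maps to index 1000 in a [−2, +1] s epoch.
* **Order ties** go to the smaller candidate; **edge-retention ties** at the
  top-5% cutoff are all kept, making the operation deterministic and
  independent of sort order.
* **Filtering** is zero-phase (forward–backward Butterworth), preserving
  event alignment at the cost of doubled effective order; resampling uses an
  anti-aliased FIR decimator.
* **Stability repair** in `build_var_coefficients()` rescales only the
  diagonal self-terms; couplings are the quantity under study and are never
  silently altered there. Graphs whose off-diagonal structure alone is
  explosive fail with the offending magnitudes named.

## 5. Graph-metric conventions

* Node strength uses the directed matrix: S_in(i) = Σ_j F_{j→i},
  S_out(i) = Σ_j F_{i→j}, S = S_in + S_out.
* The weighted clustering coefficient's triple product is inherently
  undirected, so its input is symmetrized as (F_{i→j} + F_{j→i})/2; the
  symmetrization is isolated in one place so a directed variant could be
  substituted.
* "Path length as inverse of cumulative weight" is read as *summing per-edge
  inverse weights* along a path — the standard weighted-shortest-path
  construction. The alternative (inverting a path's summed weight) is not a
  metric and breaks shortest-path optimality.
* Disconnected graphs: global efficiency uses 1/∞ = 0 for unreachable
  pairs; characteristic path length averages over reachable pairs only and
  carries a `disconnected` flag. Both remain finite and comparable across
  sparsified networks.
* Modularity is deliberately not implemented: no formula or community
  algorithm is specified in the analysis this package operationalizes, and
  guessing one would be worse than omitting it.

## 6. Statistical design

* **Tier 1** (whole-graph metrics): Welch t-tests per band, condition and
  window — robust to unequal group variances.
* **Tier 2** (node metrics): classical repeated-measures mixed ANOVA with
  group between subjects and intrinsic network (not individual channels) as
  the within-subject "region" factor — seven levels keep the design
  complete and balanced within subject and match the granularity at which
  results are interpreted. Node values are averaged within network per
  subject before the ANOVA.
* **Tier 3**: node-level Welch follow-ups run only in cells whose tier-2
  experience effect survives FDR, then aggregated by network affiliation.
* **FDR families** pool p-values per (tier, metric, band, condition) across
  windows (and nodes for tier 3). The family definition is emitted alongside
  the results, since any such choice is partly conventional.
* **Test unit**: subjects. Trial-level pooling would multiply degrees of
  freedom but pseudo-replicates within subject; the package does not claim
  to reproduce statistics computed under other pooling conventions.
* Cohen's d is experienced minus novice with pooled SD, so higher novice
  connectivity appears as negative d.

## 7. Validation scales

The acceptance suite runs at sizes chosen to make each property testable
with comfortable margins on a single CPU: direction recovery on a 5-channel
VAR(3) with four planted 0.4-magnitude edges (n = 2000, 50 seeds), AIC order
recovery on VAR(3) pairs (n = 2000, 20 seeds, search 1–8), brute-force graph
oracles on 200 random 6-node digraphs, 500-simulation Welch/BH calibration,
and one full end-to-end run at 16 channels with 10 subjects per group in the
beta band. The whole suite and the acceptance script each complete in a few
minutes.

## 8. Known limitations

* **Pairwise only.** Conditional (multivariate) GC, spectral GC and partial
  directed coherence are out of scope; indirect influence (X→Y→Z) produces
  genuine pairwise GC from X to Z, which the direction-recovery checks
  account for by margin rather than by conditioning.
* **Filtering distorts GC.** Narrowband filtering before AR fitting is known
  to bias GC magnitudes; the pipeline follows the band-limited design it
  implements and relies on identical processing across groups for valid
  contrasts. Between-group differences, not absolute F values, are the
  supported inference.
* **Channel space.** Nodes are recording channels mapped by an atlas, not
  localized sources; volume conduction in real EEG produces spurious
  zero-lag dependence that the synthetic validation cannot exhibit.
* **ANOVA assumptions.** The classical repeated-measures decomposition
  assumes sphericity across the seven network levels; no correction is
  applied. The primary effect of interest (the two-level between-subject
  factor) is unaffected by sphericity violations.
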