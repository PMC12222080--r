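# tvgc — time-varying Granger-causality networks for event-locked EEG

`tvgc` is an R package for estimating **directed, time-resolved functional
connectivity** from event-locked multichannel EEG and comparing it between
subject groups. It was built around the kind of study design used in driving
hazard-perception research: subjects watch trials that either do or do not
contain a critical event, epochs are cut around the event, and the question is
how directed coupling between brain regions differs between groups (for
example, experienced versus novice drivers) as the event approaches and
passes.

Because such studies rarely publish raw recordings, the package ships a
first-class **synthetic-session generator** with known directed coupling, so
every stage of the pipeline can be validated against ground truth.

## The model

For two demeaned, stationary series *X* and *Y*, order-*p* autoregressions
are fitted by ordinary least squares, univariately

  X_t = Σ_{i=1..p} a_i X_{t−i} + e_t

and bivariately with the partner's lags added. Granger causality from *Y* to
*X* is the log-ratio of prediction-error variances,

  F_{Y→X} = ln( var(e_X | X past) / var(e_X | X,Y past) ) ≥ 0,

computed for every ordered channel pair, per trial, inside five overlapping
1-s sliding windows (50% overlap) spanning a [−2, +1] s epoch around the
event — at the 500 Hz analysis rate, 500 samples per window. The model order
is selected by minimizing

  AIC = n·ln(RSS/n) + 2k

over a candidate range (default 1–15; default order 12) on lead trials,
averaged across channel pairs, trials and windows.

Each resulting N×N directed matrix is summarized by weighted graph metrics:
in-/out-/total node strength, weighted clustering, global efficiency and
characteristic path length (shortest paths under inverse-weight edge
lengths), with node strengths aggregated into the seven intrinsic functional
networks (Visual, DMN, DAN, VAN, FCN, Limbic, Somatomotor). Groups are then
compared in three tiers: Welch t-tests on whole-graph metrics, mixed-design
ANOVA (group × intrinsic network, network within subject) on node metrics,
and gated node-level follow-up t-tests — all with Benjamini–Hochberg FDR at
α = 0.05 and Cohen's d (experienced minus novice).

## Worked example

A small end-to-end run — 8 channels, 4 subjects per group, 12 trials, beta
band — where the novice group's generative graph has 1.5× more and stronger
directed couplings:

```r
library(tvgc)
cfg <- pipeline_config(n_channels = 8, n_subjects_per_group = 4, n_trials = 12,
                       bands = "beta", order = 8, seed = 42)
res <- run_pipeline(cfg)

net <- res$metrics[res$metrics$unit == "network", ]
round(tapply(net$value, list(net$unit_id, net$group), mean), 3)
#>             experienced novice
#> DAN               0.991  1.388
#> DMN               0.953  1.296
#> FCN               0.949  1.312
#> Limbic            1.019  1.338
#> Somatomotor       0.974  1.128
#> VAN               0.973  1.288
#> Visual            0.982  1.215

subset(res$stats$tests, tier == 2 & metric == "s_total" & condition == "collision")[,
       c("metric", "window", "statistic", "df", "df2", "p_fdr", "stars")]
#>   metric window statistic df df2       p_fdr stars
#>  s_total    SW1  27.15621  1   6 0.002491454    **
#>  s_total    SW2  48.24817  1   6 0.002208056    **
#>  s_total    SW3  33.13798  1   6 0.002491454    **
#>  s_total    SW4  28.46607  1   6 0.002491454    **
#>  s_total    SW5  10.67730  1   6 0.017085150     *
```

The network table shows the planted group difference recovered in every
intrinsic network (novice mean node strength above experienced), and the
mixed-ANOVA experience main effect on total node strength is FDR-significant
in every sliding window. `res$gc$beta$long` holds the directed weights
(subject, condition, window, source, target, F) and `res$manifest` the
per-stage provenance.

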