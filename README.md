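# msretest

Residual ballistocardiogram (BCG) artifact reduction for simultaneous
EEG–fMRI by **joint decorrelation**, evaluated through the
**test–retest reliability of EEG microstate metrics**.

EEG recorded inside an MR scanner is contaminated by gradient artifacts,
motion artifacts, and — most stubbornly — the heartbeat-locked BCG
artifact. Since no ground-truth EEG exists inside the scanner, this
package evaluates noise reduction indirectly: microstate metrics
(duration, occurrence, coverage, transition probabilities) are highly
reliable across sessions for clean EEG, so a good artifact-reduction
setting is one that raises the intraclass correlation (ICC) between a
subject's inside- and outside-scanner recordings across a cohort. The
package is aimed at EEG–fMRI methods researchers and provides the full
chain as a tested library plus a thin command-line wrapper, exercisable
end-to-end on synthetic data with known ground truth.

## The method

R-peak-locked epochs (offset −0.2 s, duration 0.7 s) are averaged in
blocks of N = 25 consecutive epochs, which suppresses ongoing brain
activity by ≈1/N in power while preserving the heartbeat-locked
artifact. With Ĉ_art the spatial covariance of these stacked averages
and Ĉ_ref its analogue for random reference triggers, the generalized
eigendecomposition

    Ĉ_art W = Ĉ_ref W Λ,   Wᵀ Ĉ_ref W = I

orders spatial components by their artifact-to-reference variance ratio
λᵢ. The unaveraged reference covariance projected through W gives the
empirical noise-reduction ratio γ̄ (≈ N for independent epochs), and
the eigenvalues are rescaled to λ̃ᵢ = (λᵢ − 1)/γ̄ + 1, so that λ̃ = 1
means "no heartbeat-locked excess" and λ̃ = 2 means twice the power
during heartbeats. Components with λ̃ᵢ above a threshold are removed by
out-projection; because reference triggers are random, the procedure is
replicated, and a threshold sweep with an ICC ≥ 0.5 pass rule selects
the operating point.

Other modules: the standard preprocessing chain (Butterworth and
zero-phase FIR filters, gradient-artifact average subtraction,
carbon-wire-loop regression, spectral segment rejection, average
reference, bad-channel interpolation), microstate analysis (GFP peaks,
two-level AAHC clustering, template ordering, backfitting with 20 ms
smoothing), ICC(A,1) with Fisher-z aggregation and permutation testing,
BrainVision/EDF+ I/O, and a ground-truthed synthetic-data generator.

## Worked example

```r
library(msretest)

# 32-channel, 120 s synthetic recording with 3 planted BCG components
cfg <- synth_config(n_channels = 32, duration_s = 120, bcg_snr = 2, seed = 1)
sim <- simulate_recording(cfg)
rec <- sim$recording
rec
#> <eeg_recording> 32 channels x 30000 samples @ 250 Hz (120.0 s)
#>   channels: eeg=32
#>   events: 119 (1 labels)

model <- fit_jd(rec, select_events(rec, "^R$"), n_avg = 25, seed = 7)
model
#> <jd_model> 32 components, gamma_bar = 25.80
#>   rescaled eigenvalues: 2.287 2.113 1.771 1.028 1.021 1.020 1.018 1.015 ...
```

γ̄ = 25.8 sits at the averaging factor N = 25, and exactly three
components stand clear of the λ̃ ≈ 1 bulk — the three planted artifact
patterns. Rejecting at the 1.15 threshold and running the microstate
chain on the cleaned, 2–20 Hz band-passed data:

```r
res <- apply_jd(rec, model, threshold = 1.15)
res$rejected_indices
#> [1] 1 2 3

cleaned <- fir_bandpass(res$cleaned, 2, 20)
tmpl <- order_templates(aahc(gfp_peaks(cleaned, max_maps = 1000), 4),
                        canonical_templates(sim$truth$positions))
ms_metrics(backfit(cleaned, tmpl))
#>  template duration_ms occurrence_hz coverage_pct
#>         A        81.6          3.11         25.4
#>         B        78.6          2.87         22.5
#>         C        88.8          3.12         27.7
#>         D        81.9          2.98         24.4
```

The recovered durations cluster at the 80 ms generative dwell time with
near-uniform coverage, as configured. For cohorts,
`simulate_cohort()` generates twin sessions with a chosen true ICC,
`pair_reliability()` scores a session pair (per-cell ICCs, Fisher-z
means, permutation p, category), and `threshold_sweep()` /
`select_candidates()` / `cross_day_select()` run the threshold-selection
workflow.

A command-line wrapper for shell pipelines lives at
`inst/cli/msretest.R` (subcommands `convert`, `preprocess`, `jd-clean`,
`microstate`, `reliability`, `simulate`).

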