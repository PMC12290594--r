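---
title: "Joint decorrelation and microstate test-retest reliability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint decorrelation and microstate test-retest reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG recorded during simultaneous fMRI is contaminated by artifacts that
dwarf the neural signal: the gradient artifact (GA) from switching
magnetic field gradients, motion artifacts picked up by the leads, and —
hardest of all — the ballistocardiogram (BCG), a heartbeat-locked
contamination from pulse-related head and electrode motion at roughly
1 Hz and its harmonics. Because there is no ground truth for what the
"clean" EEG should look like inside the scanner, it is difficult to say
whether any given artifact-reduction step helped.

This package implements two connected ideas:

1. **Joint decorrelation (JD) for residual BCG removal.** A spatial
   filtering method that contrasts heartbeat-locked covariance against
   reference covariance through a generalized eigendecomposition, and
   rejects components whose heartbeat-locked excess variance crosses a
   threshold.
2. **Microstate-metric test-retest reliability as the evaluation
   criterion.** EEG microstate metrics (duration, occurrence, coverage,
   transition probabilities) are highly reliable across recording days
   for EEG taken outside a scanner. If an inside-scanner recording is
   denoised well, its microstate metrics should agree with the same
   person's outside recording — so the intraclass correlation across a
   cohort becomes a tuning signal for the artifact-reduction threshold,
   with no need for ground-truth EEG.

Everything is exercisable on synthetic data with known ground truth; the
generator is a first-class, tested module.

## The JD estimator

Let $X \in \mathbb{R}^{C \times n}$ be a band-limited EEG recording with
R-peak triggers. Epochs of 0.7 s starting 0.2 s before each R-peak form
a tensor $X_{art}$ (channels × epochs × samples). Blocks of $N = 25$
consecutive epochs are averaged — attenuating ongoing brain activity by
$\approx 1/N$ in power while leaving the heartbeat-locked artifact
intact — and the block averages are concatenated into
$\bar{X}_{art}$. The same construction over an equal number of uniformly
random triggers gives $\bar{X}_{ref}$. With spatial covariances
$\bar{C}_{art}$ and $\bar{C}_{ref}$, the generalized eigenproblem

$$\bar{C}_{art} W = \bar{C}_{ref} W \Lambda, \qquad
  W^\top \bar{C}_{ref} W = I$$

yields components ordered by their artifact-to-reference variance ratio
$\lambda_i$.

Averaging $N$ epochs also shrinks any non-locked variance, so raw
$\lambda_i$ are not on an interpretable scale. The package therefore
projects the *unaveraged* reference covariance $C_{ref}$ through the
filters and takes the mean diagonal as the empirical noise-reduction
ratio $\bar{\gamma}$ (close to $N$ when epochs are independent), then
rescales

$$\tilde{\lambda}_i = (\lambda_i - 1)/\bar{\gamma} + 1 .$$

Under the null (no heartbeat-locked structure) the
$\tilde{\lambda}_i$ concentrate around 1, and a threshold of 1.00
rejects about half the components by symmetry — the calibration the
acceptance script measures. A component at $\tilde{\lambda} = 2$ carries
twice the power during heartbeats as elsewhere. Components above the
threshold are removed by the oblique out-projection
$X - A_{rej} (W_{rej}^\top X)$ with patterns $A = \bar{C}_{ref} W$;
under the stated normalization this reconstruction leaves the retained
component time courses untouched and makes the removed and retained
parts variance-additive with respect to $\bar{C}_{ref}$.

Numerical choices:

* $\bar{C}_{ref}$ is shrunk toward the scaled identity with weight
  `1e-6` before the eigendecomposition. Average-referenced data are rank
  $C-1$; without regularization the whitening step fails. The weight is
  far below the scale of any interpretable eigenvalue difference.
* Per-epoch channel means are removed before averaging and covariance
  estimation, so slow drifts do not masquerade as artifact structure.
* The reference-epoch count equals the artifact-epoch count (balanced
  estimation), and reference epochs may overlap R-peak epochs — the
  method's contrast does not require exclusion, and an exclusion option
  exists (`exclude_r_overlap`) but defaults off.
* Ties at the threshold are kept, i.e. rejection requires
  $\tilde{\lambda}_i$ strictly greater than the threshold.
* Because reference triggers are random, the whole fit is replicated
  (`run_bcg_reduction`, default 10 replicates) with consecutive seeds;
  each replicate's random reference selection is shared across the whole
  threshold grid in `threshold_sweep`, which is what makes a
  "replicate" a meaningful unit traced across thresholds.

## Microstate analysis

GFP (global field power) is the population SD across average-referenced
channels at each sample. Topographies at GFP peaks — moments of high
topographic signal-to-noise — are clustered by AAHC (atomize and
agglomerate hierarchical clustering), chosen for its determinism:
starting from singletons, the cluster contributing least GEV
(GFP-weighted squared spatial correlation between members and their
prototype) is dissolved and its members reassigned to the best-matching
remaining cluster, until k clusters remain. Polarity is ignored
throughout: correlations enter in absolute value and prototypes are
dominant eigenvectors of member outer-product sums rather than plain
means, so sign flips of any input change nothing. Clustering is run in
two levels (within subject, then across pooled subject maps) to give
group templates; `order_templates` labels them A–D against built-in
analytic dipolar reference maps (a stable stand-in for published
canonical topographies; ordering only needs a consistent reference).

AAHC is greedy: on small adversarial instances (nearly parallel noisy
maps) it can land in a local GEV optimum. The test suite verifies
exact optimality against exhaustive search on most small random
instances and near-optimality in the ensemble, which is the honest
statement of what a deterministic hierarchy guarantees.

Backfitting assigns each GFP-peak map to the template with the highest
absolute spatial correlation; samples between peaks inherit the nearest
peak's label (ties to the earlier peak). Temporal smoothing with a
20 ms window and non-smoothness penalty 1 then absorbs segments shorter
than the window into the neighboring label with the higher mean
correlation over the segment, iterating to stability. The exact
smoothing objective of the established microstate toolboxes is not
published in a closed form; the implemented rule is documented here,
penalty-weighted (a short segment survives only if its own mean
correlation beats the best neighbor's scaled by the penalty), and
config-exposed. Metrics per template follow the standard definitions:
mean segment duration (ms), segments per second of assigned time,
percentage coverage, and the K×K cross-type transition probabilities
(diagonal 0). With four templates each type has exactly three
cross-type transition probabilities.

## Reliability framework

For n subjects measured in two sessions, each metric cell (template ×
metric, or transition cell) gives an n × 2 matrix, scored with the
two-way, single-measure, *absolute-agreement* ICC — ICC(A,1) in
McGraw–Wong terms — which penalizes systematic session offsets, unlike
the consistency form:

$$\mathrm{ICC} = \frac{MS_R - MS_E}
  {MS_R + (k-1) MS_E + \tfrac{k}{n} (MS_C - MS_E)}, \quad k = 2 .$$

Per-metric means aggregate the per-cell ICCs through the Fisher
z-transform (atanh → mean → tanh); cells that are inestimable (zero
variance, missing template) are flagged missing and excluded. Negative
ICCs are retained — flooring them would bias the z-means. Significance
uses a permutation test (default 1000 shuffles of the session-B subject
order, one-sided, add-one estimator), which is calibrated under the
null (verified by simulation against a uniform p distribution). Mean
ICCs are labeled poor / moderate / good / excellent at 0.50 / 0.75 /
0.90, left-closed (0.50 is moderate).

The evaluation workflow sweeps the BCG threshold over a grid (the full
grid is 1.05–1.20 in steps of 0.01, plus a "none" control row) with
replicated random reference draws, marks the (threshold, replicate)
cells whose duration, occurrence and coverage mean ICCs all reach 0.5,
ranks replicates by their longest contiguous passing run (a
deterministic surrogate for "passing over a wide and continuous range"),
and finally picks the cross-day combination minimizing the threshold
difference between days, ties to the lower thresholds. Inside-scanner
recordings are backfitted after rejection followed by the 2–20 Hz FIR
band-pass, mirroring the pipeline ordering (artifact rejection operates
on broadband data; microstate analysis on the 2–20 Hz band).

## The synthetic generator

`synth_config()` describes the study conditions: 32 channels (reduced
to 16 in the heavier simulation tests), 250 Hz, four microstate
generators with 80 ms mean dwell and gamma-distributed visit lengths
(CV 0.4), a rectified 20 Hz low-pass noise process as the GFP envelope
(GFP peaks every ~25 ms, the rate seen in 2–20 Hz band-limited EEG, so
every state visit contains peaks), 10 µV mean signal GFP, 2 µV sensor
noise, a ~1 Hz heartbeat with 50 ms RR jitter, and BCG components
modeled as fixed spatial patterns × damped-oscillation waveforms
(2–8 Hz, spanning most of the cardiac cycle) delayed 0.21 s after the
R-peak so the artifact falls inside the epoch window. Artifact
topographies are shared across a cohort (the field/head geometry that
causes BCG is broadly stereotyped) while artifact amplitude, beat
timing and beat-to-beat gain vary by subject and beat. Optional
gradient-like sawtooth artifacts (with volume triggers) and carbon-wire
channels tracking a motion source complete the noise taxonomy.

Twin-session cohorts draw per-template subject effects on the dwell
mean ($\sigma_{total} = 20$ ms split so
$\sigma^2_b / (\sigma^2_b + \sigma^2_w)$ equals the requested true ICC)
and simulate each session independently given its dwell means. What the
generator does *not* emulate: 1/f spectra, alpha rhythms, volume
conduction from realistic sources, eye/muscle artifacts, electrode
drift, or nonstationary heart rate. Passing tests therefore show the
algorithms implement their models correctly and recover planted
structure — not that real inside-scanner EEG will reach any particular
ICC.

Two measurement realities shape the recovery tests. First, GFP-peak
backfitting interpolates between peaks, so state boundaries blur by up
to half the inter-peak gap: noise-free label accuracy is just under
90%, not 100%, with peak samples themselves labeled exactly. Second, the
measured metric ICC is attenuated below the generative ICC by metric
estimation noise and by the compressive mapping from generative dwell
to measured duration; sessions of 90–120 s keep this attenuation within
the stated tolerances at the test sample sizes (n = 100 subjects for
parameter recovery, n = 12 for the threshold-sweep property, 2-minute
recordings, a 3-point threshold grid with 2 replicates — sizes chosen
to keep the full simulated study at laptop scale).

## Degenerate inputs and conventions

Sample indices are 1-based (R convention) with half-open epoch
intervals; event indices rescale by the rate ratio under resampling.
Amplitudes are microvolts everywhere; EDF physical dimensions are
converted on load. EDF export uses 1-second records and drops a
trailing partial second; the native `.rds` container is the lossless
intermediate between pipeline stages (no HDF5 bindings are required).
All-zero recordings pass spectral rejection untouched (strict
inequality against a zero median); zero-variance maps are rejected by
`spatial_corr` with an error; inestimable ICC cells propagate as
flagged-missing values, never silently as zeros. Every processing
function appends exactly one provenance entry to the recording's log.
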