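---
title: "Models and methods in betarec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in betarec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betarec)
```

betarec implements the two bespoke computations of a cross-species study of
low-beta oscillations and recognition memory: a spectral analysis pipeline
for macaque dorsolateral prefrontal cortex (dlPFC) local field potentials
(LFPs) recorded during encoding, and a behavioural analysis pipeline for a
human recognition-memory experiment in which repetitive transcranial
magnetic stimulation (rTMS) was applied to dlPFC or vertex during encoding.
Because neither the recordings nor the participant data are deposited
anywhere, both arms come with first-class synthetic-data generators that
emulate the reported phenomenology, so every downstream stage is testable
end to end.

## The LFP arm

### Signal model of the generator

`generate_trials()` builds labelled trial epochs (default −1000 to +1000 ms
around sample onset at 1 kHz, with 1000-ms noise-only baseline segments
standing in for intertrial-interval recordings). Each trial is

* 1/f background noise (spectrally shaped Gaussian noise, power exponent 1
  by default, unit RMS),
* optional 50/100/150 Hz mains components (off by default — the generator
  works at the post-preprocessing stage; turn them on to exercise
  `preprocess()`),
* a label-dependent burst: carrier drawn uniformly in the 10–15 Hz band,
  envelope zero before onset, linear rise to a 100-ms peak, exponential
  decay afterwards.

The defaults encode the reported hit/miss asymmetry: hit bursts are larger
(amplitude 1.5 versus 0.75 baseline-RMS units) and decay faster (time
constant 100 versus 200 ms), producing both the bigger post-onset low-beta
transient and the steeper post-peak gradient on hit trials. Default trial
counts are the printed completed-trial totals of the first animal
(346 hits, 118 misses). What the generator deliberately does *not* emulate:
channel covariance (trials are one synthetic channel), non-stationary
baselines, burst-shape variability beyond the carrier draw, and any
spike-related structure. Passing tests therefore demonstrate correctness of
the analysis machinery under a plausible signal model, not robustness to
every pathology of real recordings.

### Preprocessing and spectral decomposition

`preprocess()` applies a second-order IIR notch (quality factor 30 by
default, forward–backward so zero-phase) at 50/100/150 Hz and decimates to
1 kHz with anti-aliasing; synthetic data are generated at 1 kHz directly,
so this stage defaults to the identity and exists to mirror the acquisition
chain (a higher-rate mode exercises the decimator). Each trial is divided
by the RMS of its own baseline segment (`baseline_normalize()`), putting
power in baseline-RMS units, and decomposed with complex Morlet wavelets
(`morlet_tfr()`, `tfr_trials()`) on the 8–60 Hz grid in 1-Hz steps — 53
frequencies. The wavelet has a fixed number of cycles across frequencies
(7 by default; the suite also passes at 5), is truncated at ±2.5 SD of its
Gaussian envelope, and is L1-normalised so a sinusoid at a wavelet's centre
frequency has unit gain regardless of frequency. Samples within half a
kernel of either epoch edge are flagged invalid per frequency; the analysis
windows (below) keep clear of the outer edges, mirroring the move from
1000-ms epochs to 800-ms test windows.

### The permutation test

`permutation_test()` compares the 800-ms pre-onset window ([−800, 0) ms)
against the 800-ms post-onset window ([0, 800) ms), per frequency–time
cell, using the median difference (post minus pre) as the statistic. Trial
labels are permuted — by default all 2N segments are pooled and reshuffled
into two groups of N ("randomly assigned conditions"); a paired
within-trial swap scheme is also provided since the segments are paired by
construction. On each of the 10,000 default permutations only the global
maximum and minimum of the recomputed map are kept; the upper significance
threshold is the 97.5th percentile of the maxima and the lower the 2.5th
percentile of the minima (linear interpolation on sorted values), giving a
two-tailed test at the .05 level with family-wise error control by the
max-statistic argument. A `matrixwise` option implements an alternative
literal reading in which per-cell running extrema matrices are thresholded
instead; the scalar max/min reading is the default because it is the
standard construction that actually controls family-wise error. The
permutation inner loop presorts each cell once and finds both group medians
by a rank-counting pass (C++), which makes the 200-dataset calibration
experiment (`fwer_calibration()`) run in about a minute.

### Band dynamics and the gradient comparison

`significant_band()` extracts the range of frequencies with significantly
*increased* post-onset power; `band_average()` averages power over the band
and trials per label; `peak_latency()` finds the post-onset peak (earliest
sample on ties); `per_frequency_gradients()` fits an ordinary
least-squares line to trial-averaged power versus time for each integer
frequency in the band over a 150-ms window starting at the detected peak
(the study's fixed windows, 100–250 ms and 150–300 ms for the two animals,
can be requested explicitly). Slopes are in normalised-power units per ms.
`paired_t()` compares the six in-band hit slopes against the six miss
slopes (5 degrees of freedom, matching the reported test shape), and
`select_stim_frequency()` takes the midpoint of the intersection of two
subjects' significant bands — (10–17) ∩ (8–15) = 10–15 Hz, midpoint
12.5 Hz, the stimulation frequency used in the human arm.

A known limitation, documented deliberately: under an exchangeable null the
paired t across the six in-band frequencies rejects far above its nominal
level (about 45–50% in our simulations, at any trial count). Neighbouring
1-Hz wavelet rows are spectrally overlapping (bandwidth ≈ f/n_cycles ≈
1.5–2 Hz), so the six per-frequency slope differences share a common noise
component, and a one-sample t over strongly correlated "replicates" is
anticonservative. The test suite asserts the nominal-level property and the
assertion fails; we keep the behaviour because the statistic's shape is
part of the procedure being reimplemented. A label-permutation version of
the gradient comparison would be calibrated and is the natural remedy.

## The behavioural arm

### Design generator

`build_session()` reproduces the experiment's structure exactly: 3
subsessions × 15 blocks (each of beta-stimulation, random-stimulation and
no-stimulation occurring 5 times per subsession in random order), 12-sample
encoding lists of session-unique stimuli, and per block 6 match + 6
nonmatch test trials in random order with randomised left/right placement —
540 test trials. In stimulated blocks 4 of the 12 samples are targeted,
drawn uniformly from the 15 enumerated configurations with at least two
non-stimulated samples between any two targeted ones (a TMS safety
constraint; the constraint is applied between targets only, not at the list
edges, which is what the wording states). Beta blocks deliver six pulses at
80-ms intervals (12.5 Hz) starting at sample onset — the train's phase is
not stated in the source protocol, so onset-aligned is the default and it
is configurable. Random blocks place the same six pulses at the starts of
six non-adjacent 30-ms bins of the 480-ms epoch, drawn uniformly from the
462 valid bin sets. Which samples become match-test stimuli is randomised
per block, so the number of targeted match trials is emergent (≈36 of 90
per condition on average), matching the published counts in expectation;
the study's single fixed stimulus order is unpublished.

### Generative observer

`simulate_responses()` inverts the dual-process signal-detection (DPSD)
model used for analysis. On a match trial the item is recollected with
probability R (baseline minus any applicable stimulation decrement, clamped
to [0, 1]); recollection yields the highest-confidence "old" response
(level 1) — the standard generative reading of a high-threshold process, and
configurable to spread over levels 1–2. Otherwise a familiarity strength is
drawn from Normal(d′, 1) (Normal(0, 1) for nonmatch trials) and binned by
five ordered criteria into the 6-point scale; the old/new decision is tied
to the middle criterion (level ≤ 3 ⇒ "old"), so decision and rating come
from one strength draw rather than the task's two-stage touch-then-rate
response. Stimulation deltas act on targeted trials only by default; a
spillover fraction can leak a share of the decrement to untargeted trials
of stimulated blocks. The default observer (R = 0.4, d′ = 1.85, criteria
2.0, 1.55, 1.175, 0.75, 0.3) is calibrated to the printed behaviour of the
task — about 85% overall accuracy with a false-alarm rate near 12% — and the
default dlPFC effect is a 0.15 recollection decrement on beta-targeted
trials, the direction and approximate size implied by the reported
within-block contrast.

### ROC construction and DPSD fitting

`build_roc()` cumulates from level 1 ("absolutely certain old") outward,
the direction in which the model equations accumulate "old" responses:
point *i* is (proportion of lures ≤ *i*, proportion of targets ≤ *i*) for
*i* = 1..5; the sixth point is (1, 1) by construction and excluded. The
source text's prose description starts the cumulation "at confidence level
6" while also defining level 6 as most-confident *new*; we treat that as an
internal coding reversal and provide a `direction` flag for data coded that
way.

`fit_dpsd()` minimises the summed squared residuals of all five points in
both coordinates under

$$p_{FA} = \Phi(-c_i), \qquad
  p_{hit} = R + (1 - R)\,\Phi(d'_F - c_i),$$

with lure recollection fixed at 0 and unit familiarity SD. R is fitted on
[−1, 1] first; a negative optimum triggers the documented refit rule (R
fixed to 0, model refit for F and criteria, `refit_applied` flagged). F is
bounded below at 0. Criteria ordering is enforced by reparameterising as a
base criterion plus positive decrements; optimisation is bounded
quasi-Newton (L-BFGS-B) from six starts (R ∈ {0, 0.25, 0.5} × F ∈
{0.5, 1.5}) with criteria initialised from the probit transform of the
observed false-alarm rates. Observed rates of exactly 0 or 1 are used as-is
(least squares needs no log-linear correction); a fully degenerate ROC (all
five points identical) is fitted but flagged with a warning. Noise-free
model-generated points are recovered to better than 10⁻³ and the optimum
beats random admissible parameter draws in the suite's checks.

Small-sample behaviour worth knowing: at the within-block stratum sizes of
this design (≈36 targeted match trials against 90 lures) the
least-squares R estimate has a sampling SD near 0.23 and a modest downward
bias, and because R and F trade off, a stratum with truly lower R shows a
small spurious negative F difference (≈ −0.07 here). Group comparisons of
*differences* are the reliable read-out at this scale; single-participant
index values are noisy. This is also why a 9-participant cohort reproduces
the qualitative targeted-versus-untargeted pattern in roughly three
quarters of simulated cohorts rather than nearly always — the aggregate
direction across cohorts is unambiguous.

### Index tables

`within_block_indices()` computes R+/R−/F+/F− per participant for the beta
and random conditions: targeted and untargeted match trials are each fitted
against the *same* false-alarm base, all 90 nonmatch trials of that
condition's blocks (nonmatch trials have no targeted identity; a
blocks-only restriction is configurable). The no-stimulation condition has
no targeted stratum and is rejected. `between_block_indices()` fits one
ROC per condition: targeted match trials only for beta and random, all
match trials for no-stimulation, each against the condition's nonmatch
trials. `hit_rate()` counts hits among match trials only. The repeated
measures / mixed ANOVAs applied to these tables in the original analysis
are standard off-the-shelf statistics and are intentionally not
reimplemented; `write_index_table()` exports tidy long-format CSVs for any
statistics package, and `paired_t()` covers the single paired test the
pipeline itself reuses.

## Orchestration, reproducibility and problem sizes

`run_lfp_arm()` and `run_behavior_arm()` chain the stages with per-stage
seeds derived deterministically from one master seed, echo the full
configuration into run logs, and write tidy CSV/JSON reports; identical
seeds give byte-identical results. `run_config()` carries the study's
defaults (8–60 Hz, 800-ms windows, 10,000 permutations, α = .05, 480-ms
samples, six pulses at 80 ms, 30-ms bins, 12-item lists with 4 targets,
3 × 15 blocks, 9 participants per site). The test suite and the
reproduction script run reduced but statistically meaningful sizes chosen
to keep the whole suite in the tens of minutes: the family-wise-error
calibration uses 200 null datasets of 20 trials on a 10-frequency ×
100-timepoint grid with 1,000 permutations; parameter recovery uses 100
simulated participants at 5,000 + 5,000 trials; cohort-effect recovery uses
200 cohorts of 9 participants at the full 540-trial design; the gradient
power study uses 50 replicates at the full printed trial counts. Exhaustive
permutation enumeration verifies the sampled test on toy instances, and
brute-force subset enumeration verifies the two scheduling combinatorics
(15 target configurations, 462 pulse-bin sets).

## Numerical choices, edge cases

* Percentiles use linear interpolation on sorted values (R's default
  quantile type 7).
* Median of an even-sized group is the mean of the two middle order
  statistics; the C++ kernel and `stats::median` agree exactly.
* Ties in `peak_latency()` resolve to the earliest time.
* `paired_t()` returns t = 0, p = 1 with a `degenerate` flag for identical
  vectors, and errors on constant non-zero differences (infinite t).
* Zero-RMS baselines, empty strata, missing conditions, Nyquist violations,
  non-fitting pulse trains and infeasible schedules are all rejected with
  messages naming the violated constraint.
* Uniform sampling of schedules is by enumeration of the full admissible
  set followed by a single uniform draw, so uniformity is exact by
  construction and verified empirically in the suite.
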