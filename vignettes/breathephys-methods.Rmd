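---
title: "Methods: breathing-cycle discrimination and electrophysiology quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breathing-cycle discrimination and electrophysiology quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`breathephys` implements two analysis families that recur in studies of
neurodevelopmental mouse models: (i) discrimination of animal groups from
whole-body plethysmography via the distribution of inter-breathing-cycle
intervals, and (ii) quantification of cellular electrophysiology — spike and
postsynaptic-current (PSC) detection, population bursts, charge densities,
GABA-A driving force, and mGluR-dependent long-term depression (LTD). This
vignette explains each model, its assumptions, the tunable parameters, and the
design decisions taken where the procedures left choices open. Every synthetic
readout quoted here is computed by the package's own tests or the acceptance
script; nothing is asserted that the code does not reproduce.

## 1. Breathing-cycle pipeline

A plethysmography trace $s(t)$ (arbitrary signal units, uniformly sampled) is
reduced to inter-breathing-cycle intervals in four steps.

**Trinarization.** Each frame is coded
$$b(t) = \begin{cases} +1 & s(t) > \theta_+ \\ -1 & s(t) < \theta_- \\ 0 & \theta_- \le s(t) \le \theta_+ \end{cases}$$
with defaults $\theta_+ = 0.15$, $\theta_- = -0.4$ signal units. The
inequalities are strict: a sample exactly at a threshold codes 0. The
asymmetry reflects the asymmetric inspiration/expiration deflections of
whole-body plethysmography; both thresholds are instrument-dependent
parameters (`upper`, `lower`), not constants of nature.

**Smoothing.** A centered moving average of 25 frames is applied to $b(t)$ and
the result re-trinarized by sign (positive → +1, negative → −1, zero → 0).
Two decisions are ours: the window is *centered* (an odd width, truncated at
the series edges) because the purpose is to suppress local threshold flicker,
not to delay the signal — a trailing window would shift every onset by half a
window; and means within $10^{-12}$ of zero are treated as exact zeros so that
balanced windows are not classified by floating-point residue. The window is
kept in frames (not seconds) as a parameter, since no frame duration is
canonical.

**Cycle onsets.** The first frame of each maximal run of +1 codes is a
positive-cycle (inspiration) onset; −1 runs give negative-cycle onsets. A run
touching the first frame counts, with onset at frame 1 (indices are 1-based
throughout).

**ICI.** The inter-breathing-cycle interval is the time between onsets of
consecutive *positive* cycles that have at least one negative-cycle onset
strictly between them; positive pairs without an intervening expiration are
skipped as flicker. A `basis = "negative"` switch computes the mirrored
definition, which in practice gives statistically indistinguishable samples.
When a positive pair brackets several negative cycles it still yields exactly
one interval — the rule is "at least one", and we implement it literally.

## 2. Group discrimination

**Cliff's Delta.** The distance between two animals' ICI samples is the
nonparametric effect size
$$\delta(A, B) = \frac{\#\{(x,y): x > y\} - \#\{(x,y): x < y\}}{|A|\,|B|},$$
computed with exact pair-count semantics (ties contribute zero). The
production implementation counts via sorted samples in
$O((n+m)\log(n+m))$; the test suite verifies it against brute-force
enumeration over all pairs for a thousand random sample pairs, along with
antisymmetry, the $[-1, 1]$ bounds, and invariance under strictly increasing
transforms.

**Distance for clustering.** $\delta$ is signed, so it is not itself a metric;
we cluster on $|\delta|$ (high similarity = low distance) and retain the
signed matrix for reporting.

**Clustering.** Each animal is represented by its row of the $|\delta|$
matrix — its distance profile to every animal, diagonal included — and
agglomerative clustering is run on the cosine distances between these
profiles, cut at $k = 3$ clusters by default (matching a three-nominal-group
design). The linkage criterion is a free choice; we default to average
linkage, a robust choice for non-Euclidean dissimilarities, with complete,
single, and Ward (on a classical-MDS embedding, since Ward assumes Euclidean
geometry) available. If all animals have identical samples the distance rows
are zero vectors and the cosine distance is undefined; this raises a
degenerate-input error rather than an arbitrary answer.

**Significance.** Under random classification each of a group's $n$ animals
falls in any of three clusters with probability 1/3, so the count $c$ of
animals in a designated cluster is Binomial$(n, 1/3)$. For each true group we
report the exact upper tail $P(X \ge c)$ at its majority cluster — no normal
approximation. The success probability stays 1/3 (three possible choices)
even when $k \ne 3$; `n_choices` exposes the alternative. When two nominal
groups share one ICI distribution, the $k=3$ cut splits their pooled cluster
arbitrarily; the stable conclusion (recovered by the acceptance checks) is
that only two populations separate with significance, the distinct group
owning one cluster outright with $p = (1/3)^{10} \approx 1.7\times10^{-5}$ at
$n = 10$.

## 3. Event, burst, and synchrony quantification

**Detection.** Spikes and PSCs are threshold crossings at
$3 \times \mathrm{SD}$ of the recording noise (the SD is estimated from an
event-free window the caller designates, e.g. a bath recording). Deviations
are measured from a running-median baseline (200 ms default) so that events
riding a slow elevation are still seen; a 1 ms boxcar is applied to the
*detection statistic only* to keep broadband noise from chattering across the
threshold (amplitudes and charges are measured on the raw trace). An event
extends until the deviation falls below half threshold, and a new event cannot
start within a refractory time (5 ms for PSCs, ~2 ms recommended for spikes)
of the previous event's end. Per event we report the peak amplitude and the
charge — the integral of $|s(t) - \text{local baseline}|$ over the event
extent, with the local baseline the median of the 50 ms preceding onset. The
detection threshold rule fixes only the crossing criterion; the extent,
baseline, and refractory rules are our decisions and are exposed as
parameters.

**Drug effects.** Event frequency is measured in ordered baseline, drug, and
washout windows; the normalized effect is freq(drug)/freq(baseline) (< 1
inhibition, > 1 excitation). A recording passes washout control only if the
washout frequency returns to within ±20% of baseline.

**Bursts.** A population burst is at least 3 detected events riding a baseline
elevation of at least 60 pA. Candidate epochs are maximal runs where the
running-median baseline deviates from the quiet level (whole-trace median of
that baseline) by ≥ 60 pA in the event polarity; each epoch is re-checked
against its own pre-epoch baseline, expanded to the surrounding half-elevation
extent (the running median erodes a plateau by up to half its window on each
side, and event counting corrects for the same erosion), and kept if it holds
≥ 3 event onsets. Burst charge, peak amplitude, duration and charge density
(charge/duration) are measured against the pre-epoch baseline. The criterion
fixes only "≥ 3 events" and "≥ 60 pA"; the baseline estimator and the epoch
extent are our decisions, stated here because no standard exists.

**Charge density and E/I balance.** CD = Σ(per-event charge)/duration, in
pC/s; normalization "to control" always divides by an explicitly supplied
control-group mean, never an inferred one. The inhibition/excitation balance
of a cell is CD(sIPSC)/CD(sEPSC).

**Paired synchrony.** Dual-recording traces are binned at 10 ms before
correlating, so the zero-lag Pearson coefficient reflects event co-occurrence
rather than within-event kinetics; raw-sample correlation would be dominated
by the kernel shape. The cross-correlogram over ±0.5 s uses the same bins.

**Recording QC.** Cells are excluded when the holding-current magnitude at
−70 mV exceeds 30 pA (P0) or 40 pA (P15), or when holding current or input
resistance drifted more than 15% during the recording. The age-specific
bounds are read as magnitude bounds (holding more negative than −30/−40 pA ⇒
leaky seal); the P15 bound is quoted as a −40 to −50 pA range in the
underlying protocol and we default to its permissive end. Every exclusion
carries exactly one triggering rule.

## 4. Biophysics

**DF_GABA from single-channel I/V.** In cell-attached recordings of single
GABA-A channels, the mean open-channel current is collected at imposed
potentials from −100 to +60 mV in 10 mV steps, with at least 20 openings per
potential (fewer raises a QC flag). Potentials are stored in the −Vp
convention, in which the fitted zero-current potential *is* the driving force
DF_GABA: positive values mean depolarizing GABA action. The default fit is
ordinary least squares on $I = g (V - V_{rev})$; because real curves can
rectify, a quadratic option is provided whose reversal is the root nearest the
recorded span (whether the original fits were linear is not documented, so
both are offered, linear first for parsimony). A reversal outside the
recorded range ± 20 mV is flagged as extrapolated.

**fEPSP slope and LTD.** The slope of a field EPSP is the linear-regression
slope over the samples between 30% and 70% of the baseline-to-peak amplitude
on the rising phase (mV/ms). The peak is the extremum inside a caller-set
post-stimulus window (stimulus artifacts should be blanked by choosing the
window). Slopes are normalized to the mean over the final 10 minutes before
drug onset — the protocol requires ≥ 20 min of stable baseline as an
*inclusion* criterion but does not fix the normalization span, so we chose the
closest stable stretch. LTD is summarized as the mean ± SEM of the normalized
slope in the early window (20–25 min after DHPG washout) and the late window
(50–55 min).

## 5. Synthetic data: what it emulates, and what it does not

All generators draw from a single explicit integer seed and restore the
caller's RNG state; fixed seed means bit-identical output.

**Breathing cohorts.** Each cycle is a positive half-sine (inspiration, 50 ms,
amplitude +1) then, after a 20 ms gap, a negative half-sine (expiration,
50 ms, amplitude −1), at 1000 Hz. No sampling rate or physical unit is
canonical for plethysmography, so units are arbitrary "signal units" scaled to
the ±0.15/−0.4 thresholds. ICIs are log-normal — strictly positive and
right-skewed like real inter-breath intervals — with per-group medians
(defaults 0.3 s for the control-like group, 0.45 s for the two mutant-like
groups, emulating slow-breathing phenotypes) and a shared log-SD of 0.35,
truncated below a feasibility floor (cycle footprint plus two smoothing
windows) so cycles never overlap the smoothing kernel. Ground truth is
returned in sidecar tables: the generator computes analytically, from the
cycle template's threshold crossing and the smoothing half-width, the exact
frame the detection chain fires at, so zero-noise recovery is exact by
construction and tests never re-derive the truth. What this does *not*
emulate: apneas, sighs, movement artifacts, baseline drift, or within-animal
nonstationarity — passing tests show the pipeline recovers what it was pointed
at, not that it is robust to every artifact of a real chamber.

**PSC trains and pairs.** Events are Poisson with gamma-distributed
amplitudes (mean 30 pA, SD 8 pA), rendered through a biexponential kernel
(rise 1 ms, decay 5 ms) plus white Gaussian noise (2 pA). Pairs share a
configurable fraction of events (shared pool of rate $rc$, independent pools
of rate $r(1-c)$ each), so the expected shared fraction equals the requested
correlation. Population bursts are event clusters (≥ 35 ms apart within a
burst, so each stays individually resolvable at the detector's re-arm time)
riding a raised-cosine plateau, synchronized across a pair. An optional
`min_separation` thins background events for perfect-recovery fixtures.
White noise is spectrally flatter than real recording noise; real mEPSC
amplitude distributions are heavier-tailed; overlapping events are
deliberately rare here and common in epileptiform activity.

**I/V and LTD series.** I/V datasets follow $I = g(V - V_{rev})/1000$ (g in
pS, V in mV, I in pA) with per-opening Gaussian noise averaged over the
openings; defaults (g = 20 pS, noise 0.2 pA, 17 potentials × 20 openings) give
reversal recovery well within 2 mV. LTD series hold baseline at 1, dip during
the 5-min drug application, recover linearly to the early level by 20 min,
hold it through 20–25 min, relax linearly to the late level by 50 min and hold
it; the early/late defaults (52.18% and 77.83% of baseline) are calibrated to
the depression levels reported for control tissue, and the mutant-like
defaults (80%/78%) express the attenuated early component with a preserved
late component. At zero noise the window means equal the configured levels
exactly by construction.

**Study-level defaults.** The end-to-end electrophysiology run uses
per-genotype defaults chosen once for the qualitative physiology they emulate:
agonist rate multipliers 0.5 (control-like: GABA inhibits) vs 1.5
(mutant-like: GABA excites); sEPSC/sIPSC rates 2/4 Hz vs 4/1.5 Hz, pushing the
I/E charge-density ratio below control; bursty-cell probabilities 0.30, 0.81
and 0.17 for control, mutant and pretreated-mutant groups; pair correlations 0
vs 0.4; DF_GABA group means −5 mV (slightly hyperpolarizing), +15 mV
(depolarizing) and −35 mV (strongly hyperpolarizing under NKCC1 blockade),
with 3 mV between-cell SD. The DF_GABA group means are figure-level values
not printed numerically in the underlying report, so these are the package's
own choices expressing the reported ordering.

## 6. Numerical choices and problem sizes

Frame indices are 1-based. The smoothing zero-tolerance is $10^{-12}$;
cosine similarities are clipped into $[0, 1]$ before conversion to distances.
Binomial tails use the exact distribution function. Charge integration is a
Riemann sum on the sampling grid; tests verify 1%-level invariance under
resampling to a finer grid. Interval ground truth is frame-quantized at
generation so recovered and planted ICIs agree to the last bit (interval
comparisons allow $10^{-12}$ for the unavoidable multiply-vs-divide ulp).

The shipped tests and the acceptance script use deliberately modest problem
sizes — cohorts of 2–10 animals per group with 25–60 s traces, 6–30 s PSC
recordings at 5 kHz, 100-seed I/V recovery runs — chosen so the whole suite
runs in about a minute on a laptop while every statistical check retains
comfortable margins. Scaling the same configs up only tightens the margins.

## 7. Known limitations

- Event detection is threshold-based by design (that is the procedure being
  implemented); heavily overlapping PSCs are merged, and deconvolution or
  template matching is out of scope.
- The burst baseline estimator (running median) erodes plateaus shorter than
  its window; bursts briefer than ~100 ms with the default 200 ms window will
  under-report elevation.
- EDF input is not supported; traces are exchanged as CSV (`time`, `value`).
- The binomial significance model assumes equally likely random assignment to
  three choices; it is a null for *random classification*, not a model of the
  clustering algorithm's own bias.
- Generator realism is statistical, not biophysical: no conductance-based
  neuron or respiratory mechanics models are involved.
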