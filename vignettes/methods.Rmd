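---
title: "Models and methods behind gonogophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gonogophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogophys)
```

## The experimental setting

`gonogophys` analyzes head-fixed Go/No-Go visual discrimination sessions.
Each trial presents a static grating during a *waiting period* (0.7 s in the
standard protocol, 0.5 s in a variant) and a drifting grating during an
*answer period* (2.2 s or 2.4 s). Licking during the answer period of a Go
trial is rewarded (hit); withholding on a No-Go trial is a correct rejection
(CR); licking on a No-Go trial is a false alarm (FA); licking during the
waiting period has no consequence. Single units are recorded in V1 and in
frontal cortex, optogenetic manipulation is interleaved in 20-trial blocks,
projection neurons are identified by phototagging (400 light pulses of 5 ms
at 0.5 Hz), and population activity can additionally be monitored by fiber
photometry digitized at 200 Hz.

Because such recordings are rarely shareable, the package pairs every
analysis with a seeded synthetic-session generator that reproduces the
statistical structure the analyses assume. Every analysis stage is therefore
testable end to end without any recorded data.

## Behavioral metrics

Hit rate is $N_{hits}/(N_{hits}+N_{misses})$, FA rate
$N_{FAs}/(N_{FAs}+N_{CRs})$, and discriminability
$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{FA rate})$.
Extreme rates of 0 or 1 make $d'$ infinite; `compute_dprime()` clips them to
$1/(2N)$ and $1-1/(2N)$ with $N$ the relevant trial count (the standard
log-linear correction). Whether the original analyses used a correction is
not documented, so the clipping rule is an explicit package decision and the
trial counts are required whenever it engages.

Lick latency is the first lick within 1 s of stimulus onset, summarized per
session by the median across trials (midpoint convention for even counts).
In trained animals this median sits near 0.45–0.5 s even with a 0.7-s
waiting period, which motivates the key windowing convention below.

## Firing-rate indices

All waiting-period statistics use the **first 0.5 s** of the waiting period
(`[0, 0.5)` s from stimulus onset), because anticipatory licking begins near
0.5 s; the baseline window is the 0.2 s before onset. All windows are
half-open `[t0, t1)` so boundary spikes are never double counted.

For per-trial rates $R$ (spike count / window length), condition means feed
three ratio indices:

* selectivity index $SI = (R_{Go}-R_{NoGo})/(R_{Go}+R_{NoGo})$,
* modulation index $MI = (R_{CR}-R_{FA})/(R_{CR}+R_{FA})$, computed on
  No-Go trials and reported only for sessions with more than 15 FA trials,
* response index $RI = (R_{evoked}-R_{baseline})/(R_{evoked}+R_{baseline})$
  per outcome class.

Ratio indices are bounded in $[-1, 1]$, antisymmetric under swapping the
two conditions, and invariant to common rate rescaling. Condition means are
means of per-trial rates, not pooled spike counts — the source convention is
ambiguous, and per-trial means keep trials equally weighted regardless of
duration bookkeeping; this is configurable in the sense that the per-trial
rates are exposed (`trial_rates()`) so any pooling can be recomputed.

Per-unit significance uses Wilcoxon tests from base R (`wilcox.test`): a
two-sided rank-sum between condition rate vectors for SI/MI (sidedness for
MI is not documented at the source; two-sided is the conservative choice),
and signed-rank tests for inclusion filters. V1 units enter analyses when
the mean waiting-period rate exceeds 0.5 spikes/s *and* evoked rates beat
baseline one-sidedly at P < 0.05; frontal units when evoked differs
two-sidedly from baseline. All-tied inputs are reported as "degenerate"
exclusions rather than errors.

The early/late decomposition recomputes SI and MI on `[0, 0.1)` and
`[0.1, 0.5)` s. Because rates come from raw spike times, no bin straddles
the 0.1-s boundary.

Laser effects use two conventions: the behaving-task *relative* change
$(R_{on}-R_{off})/R_{off}$ per condition (Go, No-Go CR, No-Go FA, the FA
case gated on >15 FA trials in both laser conditions), and the passive
*symmetric* index $(R_{on}-R_{off})/(R_{on}+R_{off})$ with rates averaged
over all orientations.

Population PSTHs (default 10-ms bins, optional Gaussian smoothing, σ
configurable since the source smoothing is unspecified) are normalized per
unit by the maximum peak across conditions before averaging, so every unit's
strongest condition peaks at 1.

## Orientation tuning

Tuning curves are per-direction means of drifting-period rates (the 2-s
drifting epoch; the 0.5-s static epoch is excluded). The orientation
selectivity index is the modulus of the doubled-angle circular resultant,

$$\mathrm{OSI} = \frac{\sqrt{\left(\sum_i R(\theta_i)\sin 2\theta_i\right)^2
+ \left(\sum_i R(\theta_i)\cos 2\theta_i\right)^2}}{\sum_i R(\theta_i)},$$

which is 0 for a flat curve and 1 for a response confined to one
orientation. Units enter laser comparisons only when, laser-off,
OSI > 0.08, the responsiveness $t$ (mean/s.e.m. at the preferred direction)
exceeds 2, and the peak rate exceeds 2 Hz. "Preferred" is the argmax
direction of the mean curve with ties broken toward the lower index; using
the best direction rather than pooling opposite directions is the package
default because it needs no assumption about direction symmetry.

## Waveform classification

Mean waveforms are trough-aligned, averaged over the overlap support, and
cubic-spline interpolated to one tenth of the raw sampling interval (the
interpolation factor is configurable; the source states only that waveforms
were interpolated). The width of the post-trough positive peak at half of
its maximum (linear interpolation between samples at the crossings)
classifies units: narrow-spiking below 0.35 ms, broad-spiking at or above
it. The boundary value itself counts as broad; widths are invariant to
amplitude scaling and time translation, and the classification is stable
across interpolation factors ≥ 4 on the synthetic library.

## Phototagging

A unit is tagged when (i) the stimulus-associated spike-latency test yields
P < 0.01 and (ii) the Pearson correlation between mean waveforms of
laser-evoked (first 10 ms after pulse onset) and spontaneous spikes exceeds
0.9.

The SALT implementation pools, over pulses, first-spike latencies in the
10-ms post-pulse test epoch and in contiguous pre-pulse baseline epochs of
the same length, into per-epoch histograms (1-ms bins plus an explicit
overflow bin for "no spike"). Jensen–Shannon divergences (base-2 logs,
additive smoothing $10^{-9}$) are computed between all epoch pairs, each
epoch is scored by its median divergence to the others, and the p-value is
the exchangeable rank of the test epoch's score among the baseline scores:
$p = (1 + \#\{D_{base} \ge D_{test}\})/(B+1)$. Under the null the epochs
are exchangeable, so this p-value is exactly uniform on its support. The
defaults carve $B = 100$ epochs from the 1000 ms before each pulse — ample
at the 0.5-Hz tagging pulse rate — giving a p resolution of 1/101, fine
enough to resolve the 0.01 tagging threshold. (A shorter baseline with,
say, 25 epochs caps the attainable p at 1/26 and can never reach 0.01;
this is why the span/epoch-count defaults matter and are reported in the
result's `config`.) Epochs that would overlap a preceding pulse's test
window are rejected at input validation.

Evoked latency is read from a 0.1-ms PSTH of the 10 ms after pulse onset:
the peak bin is located, then each bin up to the peak is compared across
pulses with the 10-ms pre-pulse mean rate by a t-test, and the latency is
the left edge of the first bin with P < 0.01. The default test is one-sided
(rate **above** baseline): with 0.1-ms bins the per-pulse rate distribution
is extremely sparse, and a two-sided test fires spuriously in early bins on
the tiny deficit created by ordinary baseline spikes, producing 0-ms
latencies. One property worth knowing: with hundreds of pulses this
procedure has power to detect the rising flank of a jittered evoked
response about two jitter standard deviations before its mean, so latency
estimates sit systematically at the early edge of the evoked distribution
rather than at its center. Degenerate bins (zero variance) map to p = 0 for
a constant nonzero elevation and p = 1 for a constant zero difference.

## Photometry

$\Delta F/F = (F-F_0)/F_0$ with $F_0$ the mean fluorescence over 2 s before
each stimulation event (1 s before stimulus onset in behaving sessions).
Per-event traces are aligned on the sampling grid; the event-averaged peak
and its latency summarize stimulation responses, and waiting-period means
grouped by outcome give the CR-vs-FA contrast in behaving sessions. dF/F is
invariant to multiplicative gain on the raw trace, and events with
non-positive $F_0$ or incomplete spans are skipped with a message. No
bleaching correction is applied by default (acquisitions use low excitation
power precisely to avoid it); the post-event search span defaults to the
inter-event interval.

## The synthetic generator

`simulate_behavior()` draws Go/No-Go labels i.i.d. (p = 0.5), Bernoulli
answer-period licking (defaults: hit probability 0.95, FA probability 0.5
scaled down by a `learning_level` in [0, 1], emulating the rise of CR rate
with training while the hit rate stays high), and anticipatory
waiting-period licks on hit/FA trials as a homogeneous Poisson process
(4 Hz) starting 0.3 s after onset — under these defaults the median first
lick falls near 0.45–0.5 s, matching trained behavior. The lick-rate
magnitude during the waiting period is not documented anywhere, so the rate
and onset are free generator parameters, not calibrated claims. Laser
blocks alternate off/on every 20 trials and flag the scheme's stimulus
class in on-blocks.

`simulate_unit()` realizes an inhomogeneous Poisson process with
piecewise-constant rates: baseline (default 5–10 spikes/s) everywhere,
multiplied during the stimulus by a stimulus gain (Go or No-Go), by the
laser gain on laser trials, and — only after the 100-ms early/late
boundary — by an outcome gain in CR/FA trials. Gains multiply rather than
add so the ratio indices recover $(g-1)/(g+1)$ in expectation. Per segment,
the spike count is Poisson and spike times are uniform order statistics,
which is distributionally identical to exponential inter-arrival sampling
for piecewise-constant rates and vectorizes cleanly.

`simulate_tagging_block()` adds to baseline spiking one spike per pulse with
probability `tag_reliability` at a Normal(3 ms, 0.3 ms) latency;
`simulate_tuning_session()` draws Poisson counts from an orientation-period
von Mises profile (12 directions × 14 repeats × 2 laser conditions);
`simulate_photometry()` superimposes a peak-normalized double-exponential
kernel (decay τ, rise τ/10) on a constant baseline with white noise. The
kernel is normalized on the realized sampling grid so a noise-free event has
peak dF/F exactly equal to amplitude/baseline.

What the generator does **not** emulate: correlated trial-to-trial
variability and spike-count correlations between units, slow drifts
(electrode, bleaching, satiety), bursting and refractory structure,
lick-locked spiking (except when constructed deliberately in tests),
reward-magnitude dynamics, and orofacial-movement covariates. Passing tests
therefore certify the estimators and their calibration under the assumed
statistical structure, not robustness to these real-data features.

## Numerical conventions and degenerate inputs

* Windows are half-open; times are seconds relative to stimulus onset
  (session clock for raw spike/lick times).
* Ratio indices return `NA` when their denominator is 0; d-prime clipping
  requires trial counts; missing outcome labels raise an error naming the
  trial.
* Wilcoxon p-values follow base R's `wilcox.test` (exact when n < 50
  without ties, normal approximation with continuity correction otherwise);
  degenerate all-tied inputs yield `NA` and an "excluded: degenerate"
  reason.
* Half-max crossings in waveform widths use linear interpolation between
  samples; peaks that never return to half maximum yield `NA` with a
  reason.
* All generators take explicit seeds and are byte-reproducible; the
  pipeline manifest stores MD5 hashes of every output so reruns can be
  verified.

## Problem sizes in the test suite

The shipped tests exercise parameter recovery at 200 units × ~125
trials/condition (index recovery to ±0.03 of the generative target), SALT
calibration at 1000 null units and power at 200 tagged units of 400 pulses
each, lick-control calibration at 400 null sessions, OSI agreement with an
independent complex-resultant oracle on 1000 random curves, and waveform
recovery on 60-unit libraries. These sizes were chosen so Monte-Carlo error
is several times smaller than the asserted tolerances while the whole suite
runs in a few minutes on one core.
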