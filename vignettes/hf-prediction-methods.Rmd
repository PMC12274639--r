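---
title: "Predicting hot-flash onsets from skin conductance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hot-flash onsets from skin conductance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfpredict)
```

## The problem

A hot flash (HF) is physiologically marked by a rapid rise in skin
conductance (SC) — the sweat response — that begins seconds before the
person subjectively perceives the event, then tails off gradually. If a
wearable can recognize that rising edge in real time, a just-in-time
cooling intervention can be triggered at or before the perceived onset.
`hfpredict` implements the full chain needed to study that question on
ambulatory 1 Hz SC recordings: window features tuned to the leading edge,
cost-sensitive three-class labeling, univariate logistic models behind a
robust scaling chain, and event-level measures that distinguish
*prediction* (identification before the reference onset, negative latency)
from *detection* (after it).

Everything operates on trailing windows: a window ending at time $t$ uses
only samples up to $t$, so every feature is computable in real time.

## Features

Two feature families summarize a window $y_1, \dots, y_L$ (1 Hz, so
$\Delta t = 1$ s):

**Median-subtracted integral** (30 s windows):
$\mathrm{msi} = \sum_i (y_i - \tilde{y})\,\Delta t$, with $\tilde{y}$ the
window median. It is zero for constant windows and exact linear ramps,
and positive when the window ends in an accelerating rise — precisely the
leading-edge geometry of a sweat response. It is invariant to baseline
offsets and scales linearly with amplitude.

**Curve-fit family** (60 s windows): the window's minimum-subtracted
signal $y_n = y - y_{\min}$ is fit with the biexponential
$y_c = A e^{Bx^2 + Cx}$ on the uniform grid $x \in [0, 1]$, by
Levenberg–Marquardt nonlinear least squares with analytic Jacobian
(`minpack.lm`). The six features are the grid extrema of
$y_c'$, $y_c''$ and $y_c' \times y_c''$; with $g(x) = e^{Bx^2+Cx}$,

$$y_c' = A\,(2Bx + C)\,g(x), \qquad
  y_c'' = A\,[(2Bx + C)^2 + 2B]\,g(x).$$

A window caught mid-rise fits a steeply accelerating curve, so `d2max`
(the largest second derivative) reacts earliest and hardest.

Numerical choices, since the least-squares setup is otherwise open:
starting values $A_0 = \max(y_n, 10^{-9})$, $B_0 = C_0 = 0$; bound
$A \ge 10^{-9}$; tolerances $10^{-10}$ on parameters and objective with an
iteration cap of 1024 per start (convergence takes under 50 in practice);
if the canonical start stalls in a poor local minimum — which happens on
steep spike-shaped windows — a small fixed grid of alternative $(B, C)$
starts is tried and the lowest-residual fit kept, deterministically. A
flat window has no information after normalization and is flagged
`converged = FALSE`; its features fall back to 0 with a degenerate flag so
the downstream scaler never sees non-finite values. Derivative extrema are
taken over the window's own $L$-point grid rather than by analytic
root-finding, matching the discrete object the pipeline actually has; a
denser grid is available and is used by the oracle tests.

## Labeling

Windows are labeled by their **last** timestamp relative to each
confirmed event onset, with half-open intervals throughout. Training uses
wide zones to balance classes: Class 1 for ends in $[-30, 120)$ s around
the onset, Class 2 in $[120, 240)$, Class 0 in $[-240, -30)$, everything
else excluded. Candidate events rejected on expert review contribute
Class 0 within $\pm 240$ s, deliberately teaching the model HF-like
negatives. Testing uses deployment-faithful zones: Class 1 in $[-60, 0)$
(the window a just-in-time intervention cares about), Class 2 in
$[0, 30)$, exclusion from 30 s to 20 min after onset, Class 0 elsewhere.
A window ending exactly at the onset is Class 2. When zones of several
events overlap, precedence 1 > 2 > 0 > excluded keeps onset-proximal
supervision. Night sweats — prolonged nighttime episodes — are excluded
from analysis entirely: windows near one are dropped in both modes rather
than counted as negatives.

## Scaling and the classifier

Each feature is scaled with statistics frozen from the training set only:
(1) a monotone normality transform chosen from {identity, signed log,
cube root, arcsinh} by minimizing absolute sample skewness, identity
winning ties — a reproducible, auditable stand-in for the visual
histogram inspection an analyst would do; (2) robust scaling by the
training median and IQR (linear-interpolation quartiles, stated because
conventions differ); (3) `atan` to bound outliers; (4) standardization by
the post-arctan training mean and SD. Degenerate stages (zero IQR or SD)
degrade to centering and are flagged. Test values never contribute
statistics, which a leakage-guard test asserts directly.

`hf_fit()` then fits a three-class multinomial logistic regression on the
single scaled feature, with an L2 penalty (default 0.5, the conventional
unit-strength ridge of common logistic solvers), an iteration cap of
10,000 and a fixed RNG seed for the coefficient initialization, so refits
are bit-for-bit reproducible. Class weights are uniform by default; a
config knob up-weights Class 1 for cost-sensitive training. Prediction is
the arg-max class from the stored coefficients; windows with missing
features predict non-HF and are flagged. The multinomial (rather than
one-vs-rest) formulation and the arg-max rule are design decisions;
probability thresholds are deliberately not exposed as defaults.

## Evaluation

Classes 1 and 2 both mean "HF present", so window-level confusion counts
merge them before computing sensitivity, specificity, PPV, NPV and F1;
predictivity is the fraction of true Class 1 windows called HF. Ratios
with zero denominators are reported absent, never zero. Event-level
measures scan the HF-positive windows in $[-60, +30]$ s around each
reference onset: no candidate means *missed*; otherwise only the first
identification counts, its signed latency (window end minus onset)
classifying the event as *predicted* (negative) or *detected*
($[0, 30]$). A positive window inside two events' candidate intervals is
attributed to the nearer onset. Latency is measured at the identifying
window's end — the moment the feature value becomes available in real
time. Per session, the prediction rate PR and identification rate IR
divide by the session's event count, and the identification latency IL
averages over identified events; sessions without events are excluded
from event-level aggregation rather than imputed. Aggregation across
sessions is an unweighted mean and SD per measure.

The classical baseline — an SC rise of at least 2 uS within 30 s — is
implemented as `freedman_detect()`. As printed, that criterion fires on
every sample throughout a spike, so runs of consecutive firing samples
collapse to their first sample and a 60 s refractory period suppresses
immediate re-detection; both are this package's decisions and are
configurable. Detections feed `event_outcomes()` exactly like model
positives.

## The synthetic generator

No public cohort of adjudicated ambulatory SC recordings exists, so the
generator is the test substrate. A session is baseline + slow sinusoidal
drift + events + night sweats + spontaneous SCRs + artifacts + sensor
noise, fully determined by a seed:

* **Events** arrive as a Poisson process (0.5/h) thinned to a 480 s
  minimum spacing, which keeps neighbouring train label zones from
  overlapping. Each adds `amplitude * S(t)`: a normalized logistic ramp
  reaching the peak over `rise_s`, then exponential decay with time
  constant 60–300 s. Onsets sit on the 1 Hz grid.
* **Perception lag.** The logged reference onset is perception-aligned;
  the conductance rise begins 10–40 s earlier. Ambulatory identification
  latencies around −20 s, produced by models that can only respond after
  the rise enters the window, require leads of that order, while pre-onset
  label zones starting 30 s before the marker imply they rarely exceed it
  by much.
* **Morphology patterns.** Typical participants: baseline 2 uS, spike
  amplitudes 2–8 uS, rises 10–40 s. Atypical participants: elevated
  baseline (6 uS), smaller (0.5–2 uS) and slower (30–120 s) changes —
  hence a smaller rate of change, which is what degrades the rate-of-rise
  features on this subgroup.
* **Spontaneous SCRs**: sparse nonspecific transients (8/h, 0.05–0.5 uS,
  2–6 s rise, 10–40 s recovery) unrelated to events. They are the main
  confounder: they fatten the non-HF feature distribution and are what
  keeps specificity below 1 even for good models.
* **Noise** is specified at the sensor level (SD 0.05 uS at 32 Hz); a
  trace generated directly at 1 Hz carries it divided by sqrt(32), so the
  default 1 Hz mode is statistically consistent with generating at 32 Hz
  and applying the 1-s mean filter.
* **Markers**: only 35% of events carry a participant marker, lagging the
  reference onset by a capped lognormal delay (median 15 s) — most events
  go unlogged, as in ambulatory studies. Night sweats occur rarely
  (0.02/h) in the nightly third of the clock; rectangular motion
  artifacts at 1/h.

Cohorts draw per-participant traits (pattern, baseline and amplitude
jitter) once and share them across that participant's visits; per-visit
seeds derive from the master seed. What the generator does **not**
emulate: sudomotor physiology, circadian thermoregulation, device
quantization, inter-electrode differences, or the adjudication ambiguity
of real expert review (ground-truth onsets are exact). Passing end-to-end
tests on this substrate therefore demonstrates that the pipeline
machinery is correct and that the features respond to the intended signal
geometry — not that the reported operating points transfer to real
recordings.

## End-to-end runs and problem sizes

`run_hf_pipeline()` simulates a cohort, holds out test participants
balanced across patterns, trains on pooled labeled windows from training
participants under the train scheme, evaluates every test session under
the test scheme, and reports three strata (all / typical / atypical).
The split is by participant, never by window, and a guard test asserts
no participant appears on both sides. The packaged study size is 12
participants with three 2-hour sessions each (6 train / 3 typical + 3
atypical test) — large enough for every stage to engage, small enough to
re-run routinely; the same code runs 48-h sessions by changing one
config field.

At this cohort size roughly 15–25 events back each univariate fit, and
the msi model in particular sits near the edge of identifiability: its
Class 1 zone spans rise, peak and early decay, so half its training
windows carry near-zero or negative msi, and with few events the
likelihood-optimal class-1 boundary can fall outside the observed range
altogether, yielding a model that never fires. That is a real
small-sample failure mode of the univariate design, reported as measured
rather than patched; the d2max model, whose feature is single-signed over
its zone, is stable at the same size.

## Known limitations

Univariate models only (multivariate fusion is out of scope); no
probability calibration; the arg-max rule with uniform weights is tuned
for neither maximum specificity nor maximum prediction rate; the
generator's morphology is a two-pattern idealization of what is in
reality a continuum; and all headline numbers are synthetic-cohort
analogs, not clinical results.
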