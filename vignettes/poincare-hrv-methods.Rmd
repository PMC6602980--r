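---
title: "Continuous Poincaré SD1/SD2 monitoring of heart-rate variability: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous Poincaré SD1/SD2 monitoring of heart-rate variability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poincareHRV)
```

## The problem

Heart-rate variability (HRV) is a non-invasive window on autonomic
nervous-system function: the beat-to-beat modulation of the sino-atrial node
by sympathetic and parasympathetic tone. During anesthesia both branches are
suppressed, and a bedside index of that suppression would let an anesthetist
track autonomic state continuously. `poincareHRV` implements such an index:
the Poincaré plot descriptors SD1 and SD2, computed continuously over a
sliding window from a uniformly sampled heart-rate signal, plus the
pre-induction versus maintenance stage comparison used to validate the
descriptors on cohorts.

The analysis deliberately operates on heart rate in beats per minute (pulse
rate variability), not on RR intervals: pulse-derived heart rate from a
finger sensor is available without QRS detection and is far more robust in
an operating theatre. SD1/SD2 values computed from HR and from RR intervals
are on different scales and are not directly comparable; this package makes
no attempt to convert between the two domains.

## The descriptors

The Poincaré plot is the lag-1 return map of the heart-rate series: each
value $x_i = \mathrm{HR}(t_i)$ is plotted against the next value
$y_i = \mathrm{HR}(t_{i+1})$. With differences $d_i = x_i - y_i$ and sums
$s_i = x_i + y_i$,

$$\mathrm{SD1} = \sqrt{\tfrac{1}{2}\operatorname{Var}(d)}, \qquad
  \mathrm{SD2} = \sqrt{\tfrac{1}{2}\operatorname{Var}(s)},$$

the dispersions of the point cloud perpendicular to and along the line of
identity $x = y$. SD1 captures short-term (sample-to-sample) variability,
SD2 longer-term variability; jointly they describe the ellipse
conventionally drawn over the cloud (`ellipse_geometry()`, orientation
fixed at 45°). `Var` is the unbiased sample variance (denominator
$n - 1$). Neither the descriptors' originators nor common HRV tools agree
on a single variance convention; $n-1$ is the most common choice and is
fixed here so that the independent rotated-coordinate oracle used in the
tests (plain `sd()` of $(x \mp y)/\sqrt{2}$) shares it. Two exact
identities follow and are enforced as invariants: the rotation equivalence
above, and $\mathrm{SD1}^2 + \mathrm{SD2}^2 =
\operatorname{Var}(x) + \operatorname{Var}(y)$.

The physiological attribution of SD1 and SD2 to sympathetic versus
parasympathetic tone is contested — published accounts disagree with each
other — so this package reports the descriptors numerically and attaches no
branch labels anywhere in the computation.

## The pipeline

**Standardization.** All input is brought onto a uniform 1 Hz grid before
any Poincaré computation (`resample_uniform()`, linear interpolation,
no extrapolation, grid anchored at the first sample). A uniform grid is
required for the lag-1 map to have a fixed time meaning, and a common rate
across recordings avoids artificially low variability at high sampling
rates. Beat-annotation input is first converted to instantaneous rate:
each consecutive beat pair $(t_i, t_{i+1})$ contributes
$60/(t_{i+1}-t_i)$ bpm at $t_{i+1}$ — assigning the value to the *later*
beat keeps the estimate causal, which matters for streaming. An optional
centered moving average (`smooth_window`, default off; 3 points suggested
for annotation-derived rate) emulates the smoothed instantaneous-rate
conversion tools used with annotation databases, whose exact kernel is not
standardized.

**Artifact rejection.** Ectopic beats and measurement noise are removed
with a relative-threshold rule (`filter_ectopic()`): a single forward
pass in which the first valid sample seeds a reference, a sample deviating
from the reference by more than 20% (strictly; exactly 20% passes) is
rejected, and each accepted sample becomes the new reference. The
previous-*accepted* reference is the convention of the rule's standard
citation; comparing to the previous *raw* sample would let one ectopic
drag the reference with it. Rejected samples are masked, not interpolated:
the grid stays regular and pairs are simply not formed across a gap, so a
removed artifact cannot re-enter the statistics through its neighbours.
The rule has one known failure mode, shared with any previous-accepted
relative filter: an abrupt *sustained* shift larger than the threshold
(e.g. a true step of more than 20% within one second) rejects everything
after it, because the reference can never catch up. On the synthetic
anesthesia transitions below this occurs in well under 1% of subjects; the
cohort comparison excludes such subjects with a warning rather than
imputing.

**Sliding window.** `sliding_trace()` emits descriptors at window end
times $T = t_0 + W, t_0 + W + \Delta, \dots$, each computed from the pairs
whose later member lies in $(T - W,\, T]$. The defaults $W = 20$ s,
$\Delta = 5$ s reflect the window-length sweep reproduced by
`window_length_sweep()`: at 1 Hz, windows below 20 s estimate a variance
from a handful of pairs and are dominated by noise, while longer windows
only lose time resolution. End-labelled half-open windows are the causal
choice — an emission uses only data already observed at its timestamp — and
make the batch trace identical to the online engine's output. Windows with
fewer than `min_pairs = 3` valid pairs are emitted as missing rows (never
dropped), so the trace is always a regular grid; a 1 s step is equally
supported for a faster display. `stream_engine()` is the online
counterpart: samples are pushed in time order, the artifact filter runs
incrementally with identical semantics, nothing is emitted until one full
window has been buffered (a 20 s initial delay at the defaults), and the
emission sequence is required — and tested — to be element-wise identical
to the batch trace.

**Stage comparison.** `compare_stages()` mirrors the validation analysis:
stage 1 is a 150–300 s segment of heart rate ending at anesthetic
induction, stage 2 a 300 s segment during maintenance (within minutes
15–30; default minutes 15–20, which is also the control placement). Per
metric it reports mean, median and IQR per stage and a *two-sided unpaired*
Mann–Whitney–Wilcoxon test at $\alpha = 0.05$. A paired test would be
natural for same-subject stages, but the unpaired rank-sum test is the
analysis the descriptors were validated with, so it is what the package
implements; if anything it is conservative here, since within-subject
correlation across stages reduces the effective group difference variance.
The exact null distribution is used when both groups have at most 8
observations and no ties (verified against full enumeration of all
labelings); larger groups use the normal approximation with midranks, tie
correction and continuity correction. Quartiles use linear interpolation
(R type 7) — stated explicitly because IQRs of 18-subject cohorts differ
visibly between quartile conventions.

## The synthetic generator

Real intraoperative recordings cannot ship with a package, so every layer
is exercised against a seeded generator (`generate_hr()`) chosen as the
*minimal* model with independently tunable SD1 and SD2:

$$\mathrm{HR}_t = \mu + A \sin(2\pi f t + \varphi) + e_t,$$

with $e_t$ a stationary AR(1) process with stationary SD $\sigma$ and
lag-1 autocorrelation $\rho$ (innovation SD $\sigma\sqrt{1-\rho^2}$,
initial state drawn from the stationary law, so there is no burn-in
transient), and $\varphi$ uniform. For the pure AR case the population
descriptors are closed-form,

$$\mathrm{SD1} = \sigma\sqrt{1-\rho}, \qquad
  \mathrm{SD2} = \sigma\sqrt{1+\rho},$$

(`expected_descriptors()`), which gives the estimators an analytic oracle:
the tests recover these values over the grid
$\sigma \in \{0.5, 1, 2\} \times \rho \in \{0, 0.5, 0.9\}$ on
20,000-sample series within three Monte-Carlo standard errors of 30
replicates.

Defaults emulate a healthy resting young adult and were fixed once, from
physiology: baseline 65 bpm; $\sigma = 4$ bpm with $\rho = 0.85$, which
puts the resting descriptors near SD1 ≈ 1.6 bpm and SD2 ≈ 5.4 bpm —
long-term variability several times the short-term component, as observed
at rest; and a respiratory sinus arrhythmia surrogate of $A = 2$ bpm at
$f = 0.25$ Hz (15 breaths/min). An anesthesia induction is emulated by
`inject_transition()`: from $t_0$ onward, deviations from the known
baseline are multiplied by a suppression factor $f \in (0,1]$ (0.3 in the
cohort experiments — a marked, abrupt loss of variability), optionally
with a baseline shift. `inject_ectopics()` multiplies a seeded random
subset of samples by $1 +$ magnitude and returns the indices as ground
truth for filter tests; the first sample is never injected, since it seeds
the filter reference by definition.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: non-stationary drift of baseline and
respiratory rate, gradual (rather than step) drug effects, measurement
dropouts, the asymmetric shape of real ectopic RR sequences
(compensatory pauses), and any coupling between rate and blood pressure.
Conclusions from the synthetic cohorts are about the *method*'s behavior
under known ground truth, not about clinical effect sizes.

## Cohort experiments and replicate design

The cohort experiments use 18 subjects per arm (a typical
proof-of-concept study arm), 25-minute recordings, induction at
$t_0 = 300$ s, stage 1 = (0, 300) s and stage 2 = (900, 1200) s. Under
suppression $f = 0.3$ the stage-2 medians of both SD1 and SD2 drop well
below stage 1 and both rank-sum tests reject in essentially every
replicate; resting cohorts retain the null for both metrics in slightly
over 90% of replicates — the bound implied by two roughly independent
tests at $\alpha = 0.05$ each, so this property sits close to its
threshold by construction.

`generate_cohort()` derives subject seeds as master seed $+ 1 \dots n$
(documented, so cohorts are reproducible subject by subject). A
consequence worth stating: *replicate* master seeds must be spaced by more
than the cohort size, otherwise consecutive cohorts share almost all of
their subjects and replicate-level rates become meaningless. The test
suite and the acceptance script space replicate masters 1000 apart and
keep the two arms in disjoint seed ranges.

Problem sizes throughout (1000 random series for the descriptor oracle,
30 × 9 AR recoveries at 20,000 samples, 100 streaming fixtures, 100
replicate cohorts per arm in the tests and 50 in the acceptance script)
were chosen so each estimate's Monte-Carlo error is small relative to the
tolerance it is checked against.

## Numerical choices and degenerate inputs

* Time comparisons use a 1 ns tolerance: windows are half-open by design,
  and float jitter must never move a sample across a window boundary.
* `sd2 = 0` (a cloud exactly on the identity line) makes the SD1/SD2
  ratio undefined; it is reported as `NA`, not an error.
* Fewer than 2 pairs is an insufficient-data error for whole-recording
  analysis but a *missing emission* inside a trace, because a regular
  trace grid is what downstream plotting and merging need.
* A series shorter than one window yields an empty trace, not an error;
  an empty length list in `window_length_sweep()` yields an empty result.
* Trace CSVs round-trip bit-identically at 6 decimal places; missing
  emissions are written as empty fields.
* All generation goes through seeded, state-restoring RNG scopes: the
  caller's `.Random.seed` is never disturbed.

## Worked example

```{r example, eval = FALSE}
library(poincareHRV)

# a 25-minute synthetic patient with induction at t = 300 s
cfg <- synthetic_config(duration = 1500, seed = 11)
rec <- inject_transition(generate_hr(cfg),
                         transition_config(t0 = 300, suppression_factor = 0.3))
rec <- filter_ectopic(rec)

# real-time style trace
tr <- sliding_trace(rec, window_spec(20, 5))
plot(tr)

# stage comparison across a cohort
cohort <- generate_cohort(18, cfg, transition_config(300, 0.3), seed = 1000)
ps <- cohort_stage_descriptors(cohort$recordings,
                               stage_spec(c(0, 300), c(900, 1200)))
compare_stages(ps)
```

## Known limitations

* Pulse-rate-variability domain only: no RR-interval mode, by design.
* The ±20% filter's sustained-shift failure mode (above); a clinical
  deployment would add a slow reference re-seed, which is out of scope
  here.
* WFDB support is read-only beat-time extraction from MIT-format
  annotation files; headers are not parsed, so the sampling frequency
  must be supplied by the caller.
* The streaming engine guarantees sample-ordered semantics, not
  wall-clock latency; it is a model of a real-time tool, not a device
  driver.
* Respiratory influence on the descriptors is simulated but not
  corrected for.
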