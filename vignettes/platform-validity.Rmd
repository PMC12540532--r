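---
title: "Handle vs platform force recording: the simulation model and validity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handle vs platform force recording: the simulation model and validity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftforce)
```

## The problem

Weight-perception experiments read out sensorimotor prediction from lifting
forces.  Two instruments are in common use: a force transducer embedded in a
*handle* gripped on top of the object, and a transducer embedded in the
*platform* the object rests on.  The handle records the applied grip and
load forces throughout the lift; the platform records the *reduction* in
downward force as load is taken up — but only until the object leaves the
surface, because from lift-off onward there is nothing left to unload.

That asymmetry matters most when an object is lighter than the lifter
expects.  The programmed force ramp then crosses the object's weight early,
the object pops off the surface while the force *rate* is still rising, and
the platform's view of the rate peak — and of the "first peak in force
rate", the classic index of anticipatory scaling — is truncated.
`liftforce` packages this whole measurement situation: a trial simulator
with the truncation built in, the trace-processing pipeline that extracts
the standard dependent measures, and the validity statistics (ICC(3,1),
2×2 repeated-measures ANOVA) used to compare the two methods.

## The trial model

A lift of an object with weight force $W = mg$ by a lifter expecting mass
$m_e$ is modelled as a programmed *minimum-jerk* force ramp

$$F(t) = T\,\big(10 s^3 - 15 s^4 + 6 s^5\big), \qquad
s = \frac{t - t_0}{\tau},$$

rising from 0 to the target $T = \alpha\, g\, m_e$ over rise time $\tau$,
after a quiet reach period $t_0$.  The minimum-jerk shape is the standard
smooth profile for programmed motor output; its rate peaks at the temporal
midpoint, which is exactly what makes truncation emerge: if $T > 2W$ the
weight is crossed before the midpoint and lift-off precedes the rate peak.
When the programmed plateau falls short of the weight ($T < W$, an
under-expected heavy object), a secondary linear ramp at the correction
rate models the feedback-driven force increase until the object lifts.

Channels are derived from the one latent load-force profile:

* handle load = total load / 2 (only the index finger is instrumented),
* grip = grip ratio × total load,
* platform = $\max(0, W - \text{total load})$ before lift-off, 0 after,
* photogate flips at the first sample where total load $\ge W$,
* independent Gaussian sensor noise is added per channel.

Expectation follows an exponential memory
$E_t = \lambda m_{t-1} + (1 - \lambda) E_{t-1}$ with $\lambda = 1$ by
default (pure one-back, the minimal model that produces switch effects),
initialised at the mean of the two masses.  Heaviness ratings follow the
assimilation form
$\text{scale} \times m \times (1 + \beta (m - E)/m) \times e^\varepsilon$,
with a log-normal per-participant scale, so that %-score normalisation
(which is scale-free) behaves as it does for real magnitude estimation.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| sampling rate | 400 | Hz | transducer convention for lifting studies |
| trial duration | 4 | s | occlusion-spectacle open window |
| masses | 125 / 518 | g | light and heavy 6 cm cubes (216 cm³) |
| reach delay | 0.5 | s | reach-to-grasp before force onset; provides the platform baseline window |
| rise time | 0.35 | s | typical programmed load ramp for confident lifts |
| overshoot α | 1.1 | — | programmed target slightly above the expected weight, guaranteeing lift-off for matched expectations |
| correction rate | 15 | N/s | secondary feedback ramp for under-expected weights |
| grip ratio | 0.6 | — | grip per unit load, a typical safety margin above slip |
| noise SD | 0.005 | N | Nano17-class transducer resolution scale |
| memory λ | 1 | — | pure one-back expectation |
| perceptual gain β | 0.05 | — | gives switch effects of a few %-score points |
| rating noise | 0.1 | log-SD | multiplicative magnitude-estimation noise |
| participant jitter | 0.10 | log-SD | individual differences in rise time, overshoot, grip ratio, correction rate |
| trial jitter | 0.04 | log-SD | trial-to-trial motor variability |
| rating scale SD | 0.8 | log-SD | idiosyncratic free scales |

Participant-level jitter exists so that between-participant variance is
available to the ANOVA and the ICC.  It covers overshoot and correction
rate as well as rise time and grip ratio: with a deterministic one-back
expectation the programmed target would otherwise be identical across
participants, leaving some condition cells with no participant-level signal
at all and making method agreement in those cells meaningless.

## Trace processing

All force channels are smoothed with a fourth-order zero-phase (forward–
backward) Butterworth low-pass at 14 Hz before any detection or
differentiation.  The forward–backward pass is implemented with
odd-reflection padding and steady-state initial conditions, so constants
pass through exactly (DC gain 1) and edge transients stay out of the
analysis region.  Rates use the three-point central difference, with
one-sided differences at the two boundary samples so series keep their
length.

Event conventions: onset is the first sample *strictly* above threshold
(0.2 N of total load for the handle; 0.4 N of force reduction for the
platform, which sees the full force rather than half); lift-off is the
first photogate sample; peaks take the first occurrence on ties.  The
onset thresholds are applied to the filtered signals.

The nine measures per trial: peak load force (PLF), peak load force rate
(PLFR), peak grip force (PGF), peak grip force rate (PGFR), load force at
the first prominent load-rate peak (LF1st), load phase duration from handle
onset (LPD1), peak platform force rate (PPFR), platform force at the first
prominent reduction-rate peak (PF1st), and load phase duration from
platform onset (LPD2).  Handle peaks search from onset to the end of the
trace (handles record through the hold phase); platform peaks search only
up to lift-off, because the platform physically records nothing afterwards.

Two automation choices replace the human rater of classic protocols:

* **First-peak selection** uses topographic prominence: the first local
  maximum whose prominence is at least 5% of the window maximum.
  Prominence bases are sought over the whole recorded series — the search
  window only constrains where the peak may *lie* — because the platform's
  0.4 N onset can open the window mid-rise of the first bump, and
  window-bounded prominence would then discount a perfectly real peak.
* **Truncation handling**: platform-side processing (filtering included)
  uses only the samples recorded before lift-off, and the first-peak
  search additionally stays clear of the last $3(\text{order}+1)$ samples
  of that record, the zero-phase filter's edge-transient support.
  Filtering across the lift-off clamp would otherwise round the corner and
  manufacture a local maximum exactly where a truncated rate is still
  rising, hiding the phenomenon of interest; a genuine peak inside that
  margin is the "only partially recorded" case and is reported as not
  captured.

An undetectable event yields an absent measure with a logged reason, never
an error: a missing lift-off removes duration and platform measures while
handle peaks survive, mirroring the instruments' real failure modes.

## Normalisation, trimming, aggregation

Ratings are normalised per participant to %-scores,
$(x - \bar{x}) / \bar{x} \times 100$, which average exactly zero per
participant.  The sign is chosen so heavier-than-average percepts score
positive (the transcription that makes the classic switch-effect directions
come out positive; the opposite convention is available via
`extraction_config(pct_convention = "mean_minus_score")`).

Outliers beyond ±3 SD are removed in a single pass (mean and SD computed
once on the full group, $n-1$ denominator; SD = 0 retains everything).  The
grouping scope is participant × measure × cube by default — collapsing
switch preserves switch effects while removing trace-level artifacts — and
is configurable (`trim_scope`) to per-cell, per-participant, or global.

Per-participant condition means feed the 2×2 repeated-measures ANOVA.  An
empty design cell (e.g. PF1st for light objects, where truncation removes
most trials) excludes that measure from the ANOVA with an explicit note —
the same reason platform studies conventionally drop light-object
first-peak data.

## Inference

* **ICC(3,1)**: two-way mixed, single-measure, *consistency* form,
  $(MS_R - MS_E) / (MS_R + MS_E)$ for two methods, with exact-F 95%
  confidence bounds and Koo–Li interpretation bands (poor < .50 ≤ moderate
  ≤ .75 ≤ good ≤ .90 < excellent; boundary values fall to the lower band,
  configurable).  Agreement ICC(A,1) is available behind a flag for
  sensitivity analysis.  Method ICCs compare per-participant condition
  means of PLFR↔PPFR, LF1st↔PF1st and LPD1↔LPD2, split by the four
  transition conditions; participants with either member absent drop
  pairwise.
* **2×2 RM-ANOVA** per measure, computed from the orthogonal
  within-subject contrasts: with two-level factors each effect is an exact
  paired $t$, $F = t^2$ with df (1, n−1), sphericity holds trivially, and
  partial $\eta^2 = SS_\text{eff} / (SS_\text{eff} + SS_\text{err})$ for
  the effect's own error term.  Zero-variance contrasts return flagged
  degenerate rows rather than errors.
* **Switch contrasts** (switch vs no-switch within each cube) are paired
  $t$-tests, Bonferroni-corrected for the family of two, with Cohen's
  $d_z$ by default ($d_{av}$ available; reports always name the variant,
  since published effect sizes are ambiguous about the standardizer).

## What the simulation shows — and what it cannot

Under the default conditions (29 participants, 20 trials per condition,
one-back expectation, β > 0) the simulated study reproduces the expected
phenomenology, and the test suite asserts it:

* switch effects in the expected directions for perception, PPFR and LPD2
  (heavy lifted slower/softer and felt heavier after a light lift; light
  the reverse);
* PF1st absent far more often for light than for heavy objects;
* handle–platform force-rate agreement high for heavy-after-heavy and
  clearly lower for light-after-heavy — the truncated condition — with the
  load-phase-duration comparison weakest in the same cell.

These are *mechanistic* reproductions: the generator contains the
truncation by construction, so passing tests show that the processing
pipeline and statistics recover the mechanism faithfully, not that the
empirical effect sizes of any real dataset are reproduced.  Real ICC
values depend on physiological variance components the generator only
sketches (log-normal parameter jitter, white sensor noise).  Real lifting
data also contain placement transients, torque, tremor, drift and
post-lift-off corrective dynamics, none of which are modelled; peak load
forces for grossly over-expected light objects are therefore upper bounds
(the model lets the programmed ramp run to its plateau rather than abort
on lift-off feedback).

## Numerical choices and degenerate inputs

Problem sizes throughout the tests and the acceptance script are the study
conditions themselves (29 × 81 trials, 1000 null cohorts for calibration);
a full run takes well under a minute on a single core.  Other choices:
gravity 9.81 m/s²; masses converted to newtons once at the boundary;
sample 1 sits at t = 0; empty search windows and too-short signals are
argument errors naming the constraint; a trial that never lifts is flagged,
not an error; ICC requires ≥ 5 complete pairs and errors on zero total
variance; all randomness flows from one seed through fixed per-participant
substreams, so cohorts are bit-reproducible and adding a participant never
perturbs earlier ones.
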