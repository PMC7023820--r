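---
title: "Models and methods behind pspvt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pspvt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspvt)
```

This vignette documents the scientific model implemented by **pspvt**:
the trial protocol, the response-scoring rules, the generative model of
virtual subjects and its calibration, the statistical layer, and the
numerical and design choices made where the task description leaves
freedom. It is the authoritative account of *why* the package behaves as
it does; the README shows *how* to use it.

## 1. The trial protocol

A trial is a fixed-duration session (default 6 min) tiled by
response-mapping blocks (default 2 min), alternating between *parallel*
(press the pedal on the lit circle's side) and *cross* (press the
opposite pedal) starting from a configurable `start_mode`. Stimuli
appear one at a time: the onset of stimulus $i{+}1$ is the *resolution*
of stimulus $i$ (its first correct press) plus a uniform draw on
$[\mathrm{isi}_{\min}, \mathrm{isi}_{\max}]$ (default 2–6 s). Anchoring
the inter-stimulus interval at the resolution mirrors the apparatus —
the stimulus stays lit, with a buzzer after a wrong press, until the
correct pedal is pressed — and guarantees stimuli never overlap.

Conventions, chosen once and used everywhere:

* All times are integer milliseconds from trial start.
* Blocks are half-open $[\mathrm{start}, \mathrm{end})$; a boundary
  instant belongs to the later block.
* The mode of a stimulus is the mode at its **onset**, even if it
  resolves after a block switch: the display state at onset is what the
  subject reacts to.
* A stimulus still unresolved at the nominal trial end is scored if its
  presses are in the log; sampling simply stops issuing onsets at or
  beyond the trial end.
* The uniform ISI law and its 2–6 s bounds are configuration, not dogma:
  the task description fixes only "random order and interval". The
  defaults give roughly 60–90 stimuli per 6-min trial, enough responses
  for stable per-trial indicators.

## 2. Scoring rules

The scorer joins presses to stimuli with the same semantics as the
apparatus. For each stimulus, the candidate presses are those between
its onset and the next onset; the first (non-middle) press is *the*
response, and the earliest correct-pedal press is the resolution.
Decisions the indicator definitions do not pin down, and how they were
resolved:

* **RT is first-press latency**, wrong or right. The existence of a
  separate error-correction indicator implies RT stops at the first
  press.
* **Error-trial RTs count in mean RT** — only hesitations are excluded
  by the definition. (Configurable by filtering the record table.)
* **Hesitation is judged on the first press**, with a strict
  `RT > 3000 ms` inequality: 3000 ms is not a hesitation, 3001 ms is.
* Error and hesitation are independent classifications: a hesitating
  error counts in both frequencies, but its RT feeds only the
  hesitation-length mean.
* **Error correction time runs from the first wrong press to the first
  correct press**, regardless of repeated wrong presses in between.
* The percentage denominator is the number of *responded* stimuli; an
  unanswered trailing stimulus is excluded from every denominator.
* The cross-mode effect pools non-hesitation RTs within each mode across
  that mode's blocks, and is missing if either mode has no usable
  response. Indicators never report 0 for an empty denominator — they
  are missing (`NA`, empty CSV cell).
* The three-pedal device's middle pedal is representable in logs,
  flagged by validation, and ignored by scoring (the protocol uses only
  left/right).

The sequential matcher is verified against an independent quadratic-time
oracle (for every stimulus, scan all presses) on 1000 randomised
micro-logs that include repeated wrong presses, middle-pedal noise,
stray presses and unresolved trailing stimuli.

## 3. The generative subject model

Each virtual subject is a parametric stochastic responder. Per stimulus:

1. With probability $p_\mathrm{hes}$ the response is a hesitation; its
   latency is $3000 + \mathrm{Exp}(\mu_\mathrm{excess})$ ms, so the mean
   hesitation length is the threshold plus the excess mean.
2. Otherwise the latency is lognormal with arithmetic mean
   $\mu_\mathrm{RT} \mp c/2$ (parallel/cross) and coefficient of
   variation $\mathrm{cv}_\mathrm{RT}$. The lognormal is the standard
   positive, right-skewed RT law; the published summaries give no
   dispersion, so $\mathrm{cv}_\mathrm{RT}=0.20$ is a free constant.
3. With probability $p_\mathrm{err}$ the first press is the wrong pedal,
   followed by the correct pedal after a lognormal delay (mean
   $\mu_\mathrm{corr}$, cv 0.30). Error and hesitation draws are
   independent.

The cross-mode cost $c$ is applied **centred** (${-c/2}$ in parallel,
${+c/2}$ in cross) rather than as a one-sided increment. This keeps
$\mu_\mathrm{RT}$ equal to the mode-balanced whole-trial mean that the
published group means report, so the recovered older-minus-young mean-RT
difference matches the published 95 ms even though the two groups get
different cross costs; a one-sided increment would inflate that contrast
by half the difference of the costs. The recovered cross-mode effect is
still $c$.

There is deliberately no learning, fatigue or block-order effect in the
generator, and no sex effect (no effect size was published): the model
emulates stationary subjects. Passing parameter-recovery tests therefore
shows the pipeline is unbiased for stationary responders — it says
nothing about drifts, speed–accuracy trade-offs or sequential
dependencies present in real humans.

### Calibration of the presets

The young/older presets are solved from the published ratio+difference
pairs (values in ms, probabilities as fractions):

| parameter | young | older | constraint |
| --- | --- | --- | --- |
| $\mu_\mathrm{RT}$ | 558.8 | 653.8 | difference 95 = 17 % of young |
| $p_\mathrm{err}$ | 0.0427 | 0.0897 | ratio 2.1 **and** difference 4.7 pp |
| $\mu_\mathrm{corr}$ | 1937.5 | 3487.5 | ratio 1.8 **and** difference 1550 |
| $p_\mathrm{hes}$ | 0.0015 | 0.024 | ratio 16; young value is a free constant |
| $\mu_\mathrm{excess}$ | 500 | 1800 | older hesitation length 3.0 + 1.8 = 4.8 s |
| $c$ (cross cost) | 30 | 60 | free constants (no published magnitude) |

Each ratio/difference pair is consistent:
$95/0.17 \approx 558.8$, $4.7/(2.1-1) = 4.27$ and
$4.27 \times 2.1 \approx 4.27 + 4.7$, $1550/(1.8-1) = 1937.5$ and
$1937.5 \times 1.8 = 1937.5 + 1550$. These identities are asserted in
the test suite. The middle-aged preset is the componentwise midpoint of
young and older and is flagged uncalibrated — no group-specific values
were published for it.

The young hesitation probability 0.15 % keeps the 16-fold older rate at
a realistic 2.4 %; the cross costs 30/60 ms are plausible Simon-effect
magnitudes that grow with age. Both are documented free choices, fixed
once.

### Seed discipline

Every simulation is a deterministic function of a seed, and
`simulate_trial()` restores the caller's RNG state. Cohorts split a base
seed into per-subject streams through a counter keyed on
(group, subject index), kept below $2^{31}$: the same spec and seed give
byte-identical logs, and resizing one group never reshuffles another's
draws (growing a pool keeps the original subjects as a prefix).

## 4. Statistics

* **Bland–Altman**: differences second − first; sample SD ($n-1$);
  limits mean ± $k\,$SD with $k = 1.96$ by convention (configurable);
  the band width $2k\,\mathrm{SD}$ is the repeatability range.
  `bland_altman_summary()` rebuilds the object from reported summary
  statistics, e.g. to recompute published range widths.
* **Two-way ANOVA**: the named general-linear-model procedure with an
  interaction implies Type III (partial) sums of squares for the
  unbalanced age × sex design; implemented as `lm` with sum-to-zero
  contrasts tested via `car::Anova(type = "III")`. On balanced designs
  it reduces to the textbook decomposition (asserted to 1e-8), and its
  null type-I error for the age effect is checked by simulation
  (2000 unbalanced 3×2 datasets, 0.05 ± 3 binomial SE).
* **Bonferroni pairwise**: two-sample t statistics on the pooled
  residual variance across all groups (df $= N - k$), adjusted
  $p_\mathrm{adj} = \min(1, p \times \#\mathrm{pairs})$. The published
  workflow ran comparisons only after a significant omnibus effect; the
  function computes them unconditionally and reports the omnibus gate
  separately so the conditional workflow can be reproduced.

## 5. Numerical choices and degenerate inputs

* Latencies and correction delays are rounded to integer ms and clamped
  to ≥ 1 ms; hesitation latencies stay strictly above the threshold so
  rounding cannot silently reclassify them.
* A non-hesitation lognormal draw can in principle exceed 3000 ms and be
  scored as a hesitation; at the preset means and cv the probability is
  about $10^{-14}$ and is ignored. Profiles with extreme means or cvs
  should expect this leakage.
* Zero-variance Bland–Altman input is legal (range 0); fewer than two
  pairs is an error. Degenerate zero-variance pairwise comparisons
  return $p = 1$ for equal means rather than NaN.
* An empty A×B cell is an error naming the cell (the Type III
  interaction hypothesis is not estimable); a single responded stimulus
  still scores, but an empty trial is an error.
* A block longer than the trial is accepted and truncated — the timeline
  is always a tiling of the trial.

## 6. Problem sizes used in verification

The repeatability-limit arithmetic is exact. Pipeline calibration checks
use 100 replicate cohorts (24 young / 17 older) for the group-mean
differences, and pooled samples of 600/600 (errors, corrections) and
500/500 (hesitations) subject-trials for the ratios, each compared at
3 Monte-Carlo standard errors of the estimate; random-profile parameter
recovery uses 6 profiles × 60 trials. These sizes put the Monte-Carlo
SE well below each target contrast while keeping the default test run
fast.

## 7. Known limitations

* The simulator is stationary and sex-blind; it cannot generate the
  published age × sex interaction or any learning curve.
* The middle-aged preset interpolates rather than calibrates.
* Scoring assumes the protocol's no-overlap property; logs violating it
  are still scored deterministically (window-based attribution) but are
  flagged by validation, and the scorer's behaviour on them is a
  convention, not a claim about the apparatus.
* Published F/p tables for the human cohort depend on the unavailable
  raw dataset and are out of scope; the statistics layer is verified
  against oracles and simulations instead.
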