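---
title: "Methods: simulating and scoring a visual-field-defect rehabilitation trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring a visual-field-defect rehabilitation trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfdtrial)
```

## The problem

After a stroke that damages the visual pathway, patients are often left
with a homonymous visual field defect (VFD): a hemianopia (loss of half
the visual field) or quadrantanopia (a quarter). Randomized trials of
restitutive training — repeated visual-discrimination practice aimed at
the blind field — quantify recovery with standard automated perimetry.
`vfdtrial` implements the full outcome pipeline of such a trial on
Humphrey 24-2 exams, together with a synthetic patient-cohort generator
and a headless simulator of the training protocol, so that every stage
can be exercised and validated without patient data.

## The 24-2 grid and the binocular frame

Test points sit at odd multiples of 3° on a 6° lattice; each point
represents a 6° × 6° = 36 deg² cell, which is what converts point counts
into the improved-area outcome (2 points = 72 deg², 3 points = 108 deg²).
The common binocular frame holds 52 points (26 per hemifield, 13 per
quadrant), generated row-wise: rows at |y| = 21 span |x| ≤ 9, |y| = 15
spans |x| ≤ 15, and |y| = 9 and |y| = 3 span |x| ≤ 21. Each eye-native
grid additionally tests two nasal extension points at |x| = 27 and omits
the two points on the temporal blind spot (x = ±15, y = ±3). The nasal
points are single-eye and asymmetric, so they are excluded from all
binocular scoring; at the blind-spot points the fellow eye's value stands
in, with no interpolation.

## Binocular integration

The trial outcome lives on a single field per patient and visit, built by
taking the maximum sensitivity across the two eyes at each common-frame
point. The perimeter only defines this rule for sensitivity; total
deviation (TD) and its probability category must also live on the
integrated map because the defect mask is drawn there. We carry TD and
the probability category over from the eye that supplied the winning
sensitivity (ties to the right eye). The alternative — a pointwise best
TD — was considered and rejected: it could combine sensitivity from one
eye with a deviation from the other at the same point, producing maps
that correspond to no measurable exam.

## Outcome definitions

* **Defect mask**: locations with TD probability strictly below 5%
  (categories 0.5, 1, 2 — not 5). The strictness follows the clinical
  eligibility rule.
* **Classification**: the defect side is the hemifield with the strict
  majority of mask points (an exact tie cannot be lateralized and is an
  error). The defect is a hemianopia when both quadrants of that
  hemifield are each at least 25% occupied (≥ 4 of 13 points); otherwise
  a quadrantanopia in the dominant quadrant. The 25% bar is our
  operationalization of the ophthalmologist's judgment and is
  configurable.
* **Improved area**: 36 deg² × the number of region points gaining ≥ 6 dB
  of sensitivity from baseline. The 6 dB criterion is roughly twice the
  test-retest variability of automated perimetry, which is why the
  generator's default noise SD is 3 dB. Points already at or above a
  30 dB normal ceiling at baseline are not counted as improvable
  (configurable off): a gain on an already-normal point is not a
  treatment signal.
* **MTD**: the arithmetic mean of TD over a region. Outcomes are reported
  for the *full* hemifield on the classified defect side — not the mask
  alone — so that recovery at defect borders is captured, and for the
  whole field.
* **Responder**: strictly positive MTD change.

The null behavior of the improved area is a useful closed form: with
per-point test-retest SD σ on both visits, the visit difference has SD
σ√2, so a 26-point hemifield with no true change yields on average
26 · P(Z ≥ 6/(σ√2)) improved points — about 2.0 points (73 deg²) at
σ = 3 dB. The test suite verifies the pipeline against this form by
Monte Carlo over 500–600 simulated patients.

## The statistical battery

All comparisons are two-sided and follow a normality gate: Shapiro–Wilk
at α = 0.05, applied to paired differences for within-group tests;
parametric (paired/independent t) when normality is not rejected,
nonparametric (Wilcoxon signed-rank / Mann–Whitney U) otherwise. Improved
areas, being heavily tied and skewed, are always compared between arms by
Mann–Whitney. Categorical baseline comparisons use Pearson chi-square
*without* continuity correction and the Fisher exact test with the
two-sided probability-mass rule (summing all tables, margins fixed, whose
probability does not exceed the observed table's) — these two conventions
are validated in the tests against a published trial's baseline table,
which they reproduce and the Yates-corrected variant does not.

Numerical conventions: Mann–Whitney and the signed-rank test use exact
enumeration for small untied samples (n ≤ 8) and the tie-corrected
normal approximation without continuity correction otherwise; zero
differences are dropped before signed-ranking (an all-zero difference
vector is an error, not p = 1); degenerate (constant) samples are errors
at the gate. p-values render in clinical-table style (".03", "<.001",
">.99"). The tie-corrected approximation was checked by simulation: its
type-I error on 36-deg²-quantized null outcomes is 0.050 over 2000
simulated trials.

## The synthetic cohort

The generator's defaults describe the trial structure the analysis
expects: two arms of 40 and 35 patients, block-4 permuted randomization
(the block sequence is quota-constrained so the configured arm totals are
met exactly), 56% left-sided defects, 53.3% hemianopias, ages
Normal(52, 15) truncated to [19, 80], per-arm dropout probabilities of
1/41 and 3/38, and measurement noise of 3 dB per point.

Truth maps are built from an invented but fixed normative surface —
33 dB at the innermost ring, −0.5 dB per ring outward, −0.1 dB per year
beyond age 45, clamped to [20, 40] — with the affected hemifield or
quadrant replaced by a deep defect (Uniform(0, 8) dB) and a one-column
transition band along the vertical meridian (Uniform(8, 18) dB). TD
probability categories are assigned by quantile: the smallest c in
{0.5, 1, 2, 5} with TD below `qnorm(c/100)` × the normative SD (3 dB by
default), else within-normal-limits. Under a normal-truth map this flags
5% of points at the 5% level by construction (verified by Monte Carlo);
deep-defect points land in the worst category deterministically.

Training effects are programmed per arm: each *sub-normal* (< 30 dB
truth) point of the defective hemifield truly improves with probability
`p_improve`, by a Normal(8, 2) dB gain truncated at zero. Restricting
gains to sub-normal points keeps the programmed effect identifiable —
gains at already-normal points could never be counted under the 30 dB
ceiling rule, which would break the exact parameter-recovery identity
(k programmed points → 36k deg² at zero noise) that the test suite
enforces. Default `p_improve` values (0.115 / 0.105) were chosen once to
produce improved areas of the order of 100 deg² per patient under 3 dB
noise, the magnitude regime of published defective-field training trials.
Both eyes share one truth map (the defects are homonymous) with
independent measurement noise.

What the generator does *not* emulate: the adaptive thresholding
staircase of the perimeter (exams are generated at the sensitivity-map
level), fixation losses and false-positive/negative catch trials,
learning effects across perimetry sessions, vendor normative databases,
and spatially correlated noise. Passing tests therefore demonstrate the
correctness of the scoring and analysis machinery under the stated noise
model, not clinical performance on real perimetry.

## The training simulator

The protocol is 64 trials × 6 blocks per day, 5 days a week for 12 weeks
(60 sessions, 23,040 trials), with a per-trial sequence of 700 ms blank
with beep, 150 ms stimulus, 3000 ms response window. The discrimination
task per block is drawn uniformly from orientation / rotation / depth
(the protocol lets patients choose freely; uniformity is the neutral
model). Peripheral stimuli land in the defective hemifield with 4.3 : 1
odds for the defective-field program (NV) and in the intact hemifield
with the same odds for the central-field control (NV-C); the quadrant is
uniform within the chosen hemifield (the per-quadrant weighting seen in
published training maps is simplified away; a config hook remains).
Placements are uniform over the quadrant's annular sector — 5–21°
eccentricity for NV, ≤ 5° for NV-C. The 4.3 : 1 ratio is implemented as
sampling odds, not a deterministic 43 : 10 cycle.

The simulated observer is a logistic psychometric function of the true
sensitivity S at the nearest grid point:
p(correct) = 0.5 + (0.5 − λ/2) · logistic(β(S − θ)), with a λ/2
no-response rate; defaults β = 0.5 /dB, θ = 12 dB, λ = 0.04 put
deep-defect performance at chance and intact-field performance near
ceiling. This observer is deliberately plain plumbing for end-to-end
tests — no claim of biological fidelity, no difficulty staircase, static
difficulty per program. An optional linear sensitivity growth at trained
points (dB/week) produces rising weekly accuracy for learning-transfer
analyses, which are summarized per task and week and related to scored
field improvement by Spearman rank correlation.

## Problem sizes and determinism

Every stochastic routine consumes the global RNG; the cohort generator
and program simulator re-seed from their mandatory `seed` argument, so
identical configurations are byte-identical on disk. The test suite runs
its Monte-Carlo properties at sizes chosen to keep estimates' simulation
error well inside the asserted tolerances while completing in about a
minute: 500–600 patients for the noise-only null, 10⁴–10⁵ draws for
placement and calibration frequencies, 2000 simulated trials for type-I
calibration, and full enumeration oracles only where the combinatorics
are small (2×2 tables with n ≤ 60; rank tests with n ≤ 8 per group).

## Known limitations

Only the 24-2 pattern is supported (no 10-2/30-2, no pattern deviation,
no glaucoma indices); TD probability categories are consumed as supplied
rather than derived from a vendor normative database; the defective
hemifield for outcomes is defined by the classification majority rule,
which inherits its behavior on pathological masks (balanced masks error
out by design); and the trial report implements the published battery
without covariate adjustment or multiplicity correction, which that
battery did not use.
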