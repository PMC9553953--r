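---
title: "Onset detection and histology coupling in string-pulling cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Onset detection and histology coupling in string-pulling cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringpull)
```

This vignette is the package's account of its statistical model: what each
stage computes, which parameters matter, how the synthetic cohort generator
was calibrated, and what the passing tests do and do not show about real
data.

## The measurement model

A string-pulling study records each animal twice weekly from week 9 to 18
of age for 1 minute per session. Manual annotation yields pull events
(start, end, posture, string displacement); `score_session()` reduces them
to three session metrics. Time metrics are *occupancy*: overlapping events
are merged by interval union before summing, so double-annotated frames are
not counted twice. Length is *cumulative*: displacements are summed even
when events overlap. These definitions force the invariant
0 ≤ time on hindlimbs ≤ time pulling ≤ 60 s, which the validators enforce
on any loaded table. Weekly averages use whatever sessions a week has: a
week with one recorded session contributes that session alone rather than
being dropped, which mirrors the tolerance of mixed-effects analyses for
unbalanced designs; a week with none is absent, never imputed.

## Onset statistics

**Group-level z rule.** The experimental (SOD1) group serves as its own
reference: all per-animal weekly values in weeks 9–11 are pooled, giving a
baseline mean *m* and sample SD *s* (n − 1 denominator). The weekly group
mean x̄(w) is standardized as z(w) = (x̄(w) − m)/s, and onset is the first
week after the baseline window with z(w) ≤ −0.5. The crossing is
inclusive, and a single crossing suffices: the rule is "the first point"
past threshold, with no sustainment requirement. A `sustain = k` argument
exists for sensitivity analyses but defaults to 1. All four tracked
quantities (three behavioral metrics and weight) are decline metrics, so
the threshold is applied on the negative side only; an `direction`
argument covers hypothetical increase metrics.

The −0.5 z threshold is sometimes glossed as "20 % deviation from the
group's own baseline". Algebraically the two rules coincide exactly when
s = 0.4 m, and only then; the package therefore implements them
independently — the z rule at group scope, the 20 % rule at animal scope
(first week an animal is ≥ 20 % below its own weeks-9–11 mean, inclusive
at the boundary) — and never assumes the equivalence. A property test
checks the identity at s = 0.4 m.

**Degenerate baselines.** A baseline pool with a single value has an
undefined SD (flagged `NA`); a constant pool has SD 0. In both cases
z scores are refused with a dedicated error rather than silently producing
±Inf. For genuinely noise-free data (the generator's zero-noise limit) the
analysis accepts an explicit `baseline_sd` override per metric, which is
how the noiseless end-to-end test pins the detected onset to the
programmed crossing week exactly.

**Weight.** Healthy mice gain weight over weeks 9–18, so a static
weeks-9–11 weight baseline would mask the expected growth. Weight onset is
therefore assessed against an extrapolated counterfactual: relative weight
change to week 9 is computed per animal; an OLS line is fitted to the WT
weekly means over the full observed range (fitting over 9–18 rather than
9–11 was an open choice — the longer window estimates the growth slope
with far less variance, and the window is configurable); the line is
re-anchored through the SOD1 weeks-9–11 mean at week 10 (the window
midpoint); and the z rule is applied to the deviation of the SOD1 weekly
mean relative weight from that projection, with the baseline SD taken from
the pooled weeks-9–11 deviations.

**Weekly comparisons.** Per-week two-sided Welch tests between genotypes
approximate the per-week comparison structure of a repeated-measures
mixed-effects analysis with Sidak post-hoc correction. This is an
approximation, not an equivalence: no REML model is fitted, so
within-animal correlation across weeks is not modelled; the Sidak family
is the set of post-baseline weeks tested per metric (weeks 12–18, m = 7,
under the default design). Groups with zero variance are handled
explicitly (identical means: t = 0, p = 1; distinct means: p = 0), and
weeks with fewer than two animals in a group are skipped and logged.

## Histology

Motor-neuron classification follows the marker-and-size rules: in the L5
ventral horn, NeuN⁺ somata with cross-sectional area strictly greater than
250 µm² count as motor neurons; in layer-5 motor cortex, CTIP2 expression
alone. The 250 threshold is interpreted as an *area* in µm² — as a
diameter it would be anatomically implausible for murine motor neurons —
and the cutoff is configurable. Counts are normalized to field density,
count / (1024 × 1024 px) × 10⁶, slices of one animal are averaged so each
animal is one n-value, and genotypes are compared per timepoint with a
pooled-variance unpaired t test (Welch behind a flag, matching the
common default for "unpaired t test" in GraphPad-style workflows).

Correlations between density and behavior use group means at matched
timepoints: histology weeks 7/11/15/19 pair with behavioral weeks
9/11/15/18 (behavioral testing starts at week 9 and ends at week 18, so
the out-of-range histology weeks clamp to the nearest tested week). With
four timepoints that is a 4-point Pearson correlation, reported as R²
together with the OLS slope/intercept of behavior on density; a
`per_animal` flag pairs each cross-sectional animal's density with its
matched behavioral group mean instead. Whether the original aggregated
scatter used group means or per-animal points is not knowable from a
figure alone; group means are the default because the headline R² values
are reproducible from exactly four matched means.

## The synthetic cohort generator

Because no raw cohort is publicly deposited, every stage is exercised on
synthetic cohorts from `simulate_cohort()`. The generator's defaults *are*
the study conditions: 16 WT (8 F/8 M) and 24 SOD1 (12 F/12 M) animals,
weeks 9–18, two sessions per week, histology at weeks 7/11/15/19 with 6
animals per genotype per timepoint and 3 slices per animal. Sex is
generated and carried through all tables but has no programmed effect, as
no sex difference is part of the emulated design.

The behavioral model is Gaussian: per-metric between-animal intercepts
(SD `animal_sd`) plus per-session noise (SD `noise_sd`), both sharing a
latent factor across the three metrics (correlation 0.6 — an animal that
pulls less also stands less; without this correlation the physical
constraint hindlimb ≤ pulling would be violated in several percent of
sessions, with it the constraint clamp fires in well under 1 %). The
magnitudes are free parameters of the emulation, not published values:
baselines 32 s pulling / 22 s on hindlimbs / 110 cm pulled, session SDs
4 / 3.5 / 18 and animal SDs 3 / 2.5 / 12 were chosen once as realistic
for one-minute sessions and held fixed. Negative values and
hindlimb-exceeds-pulling draws are clamped to the physical range; the
zero-noise limit is exact by construction.

The programmed SOD1 deficit is piecewise linear: flat through week 11,
then declining at `deficit_slope_sd_per_week` (default 0.5) in units of
`deficit_sd_scale` per week from `deficit_onset_week` (default 12). The
scale unit defaults to the *session-level* SD
√(`animal_sd`² + `noise_sd`²). The z statistic's denominator — the pooled
SD of *weekly* values (averages of two sessions) — is slightly smaller,
so the expected group z at week 13 sits a little below −0.5 (about −0.58
under the defaults) rather than exactly on the threshold. That margin is
what makes week 13 the *stable* first crossing: with the expectation
exactly at −0.5, sampling noise would scatter first crossings evenly
between weeks 13 and 14 and the modal detected week would be a coin flip.
The scale is an explicit config field precisely so noise-free
configurations can still program a deficit.

The weight model shares the structure: animal-level starting weights
(22 ± 1.5 g at week 9), a common growth trend of 0.25 g/week, 0.4 g
weekly measurement noise, and an SOD1 shortfall relative to the WT trend
from week 12. The default shortfall slope, 0.3 g/week, was calibrated by
simulation sweep so the expected deviation z at week 13 is ≈ −0.65:
comfortably past threshold at week 13 (any value with expected
z(13) ≤ −0.5 makes week 13 the first expected crossing) without being so
steep as to be trivial.

Histology counts are drawn around programmed means — WT constant at the
region's healthy count (M1: 32, L5VH: 13 cells/field), SOD1 declining
linearly in the programmed behavioral decline *at the matched behavioral
week* via a per-region gain (M1 couples to time pulling at 0.93
cells per s; L5VH to time on hindlimbs at 0.605 cells per s, i.e. roughly
45 % cortical and 60 % spinal loss by week 19). Defining the coupling on
the matched-week behavioral decline (not on the histology week itself)
makes the noiseless 4-point scatter exactly collinear, so the noiseless
limit r² = 1 is exact. Per-animal count SDs were the calibration target:
a brute-force sweep over noise SDs, scoring the mean 4-point R² across
hundreds of seeded cohorts, fixed M1 at 5.85 and L5VH at 4.6 cells/field
to reproduce the target mean R² values (≈ 0.91 cortical–pulling,
≈ 0.83 spinal–hindlimbs); the defaults were frozen after that sweep and
are verified by the acceptance suite at ± 0.05. Counts are emitted as
continuous expected counts truncated at zero rather than rounded
integers: the zero-noise exactness invariants (WT slices exactly at the
programmed density, noiseless r² exactly 1) would not survive rounding.
Real counts are of course integers; for the noise levels involved the
distinction is immaterial to every statistic computed.

### What the generator does not emulate

- **Pre-behavioral spinal loss.** Because density is coupled to the
  behavioral decline, the SOD1 spinal density at week 11 equals the
  healthy mean; a real cohort can show significant ventral-horn loss at
  week 11, before behavioral onset. Passing recovery tests therefore says
  nothing about detecting histological change that precedes behavior.
- **Dropout and survival**: no death or censoring is simulated, and
  exclusions are a user-supplied list, not a rule.
- **Litter, cage, and sex effects**; floor/ceiling compression of a
  60 s session beyond the hard clamp; non-Gaussian heavy-tailed session
  noise from unmotivated performances.

## Numerical choices and problem sizes

Thresholds are inclusive (z ≤ −0.5, deviation ≥ 20 %): "first point"
semantics make the boundary a crossing. The modal detected week resolves
ties toward the earlier week. Sidak adjustment is computed as
`-expm1(m * log1p(-p))`, clamped into [p, 1] so the p_adj ≥ p guarantee
holds to the last ulp. The interval union is an exact sweep over sorted
endpoints, tested against an independent 1 ms discretization oracle on
randomly generated ms-aligned event sets. Determinism is per
(config, seed): one Mersenne–Twister stream for behavior and weights, a
second (offset) stream for histology, so the cross-sectional tables do
not depend on cohort size.

The recovery studies run at the sizes a desk check needs: the onset mode
uses 100 simulated cohorts and the correlation calibration check 500,
both chosen as the smallest replicate counts at which the mode and the
mean R² are stable in repeated runs.
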