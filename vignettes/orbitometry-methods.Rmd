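---
title: "Validating virtual-reality diameter measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating virtual-reality diameter measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitometry)
library(dplyr)
```

## The problem

Can lengths measured inside a virtual-reality (VR) rendering of a CT volume
be trusted the way physical caliper measurements are? The validation design
this package implements compares two independent, blinded grader groups
measuring the *same* nine diameters on one dried skull: three graders with a
digital precision caliper on the physical specimen, four graders with a
digital VR caliper on the volume-rendered CT scan. Six diameters are
delimited by 2 mm metal bead pairs glued to the skull (measured between the
outer bead surfaces, as caliper jaws touch them), three by rigid 25 mm metal
pins. Every grader measures every location three times, giving
(3 + 4) × 9 × 3 = 189 readings.

The raw per-grader readings of the original study were never published; what
is published is the per-location summary table, group summaries and derived
percentages. The package therefore has two layers:

1. a **deterministic layer** that re-derives everything derivable from the
   embedded published summary table (`table1_fixture()`,
   `reproduce_reference_results()`), and
2. a **simulation layer** (phantom → caliper → grader simulator → statistics)
   that reproduces the *statistical structure* of the study, so the
   reliability machinery can be exercised and validated end to end.

## The synthetic phantom

`build_phantom()` rasterizes, on a voxel grid with the CT layer thickness of
0.625 mm, an ellipsoidal bone shell with two spherical orbital cavities and
the nine metal fiducials at known world positions. Anatomical fidelity is a
non-goal: the phantom exists to carry *exact ground truth* — every fiducial's
endpoints, and hence every true diameter, are known to machine precision.
World coordinates are 0-based voxel index × spacing; there is no orientation
matrix, which is adequate for a single-volume study.

Default attenuation values are air −1000, soft tissue 40, bone 1200 and
metal 3000 HU. No HU values are prescribed by the study; these were chosen
once so that the four classes are separable by simple thresholds, which is
what the automated fiducial detector relies on. The bead-pair "diameter" is
the outer-surface distance, i.e. centre distance plus one bead diameter.

CT blooming (apparent enlargement of dense metal) can be mimicked by a
separable Gaussian blur (`blooming_sigma_mm`). The default is 0: the crisp
phantom is the reference condition, and tests show that a sub-voxel blur
moves bead component centroids by less than the blur sigma. Pin centroids
are deliberately excluded from that invariant: where a pin crosses the bone
shell its blur halo is asymmetric, and the pin *endpoints*, not its
intensity centroid, are the landmarks.

True diameters default to the published per-location physical means,
rescaled per landmark group so the group means equal the published group
rows exactly (beads 37.38 mm, pins 25.01 mm); the bead per-location values
are printed at only one decimal, so the group rows carry the better
precision.

## The digital caliper

`caliper_place()` / `caliper_refine()` / `caliper_save()` implement the VR
caliper contract: two markers placed in the volume, repositioning allowed
until the measurement is saved, the distance and the *number of adjustments*
logged. Zeroing the physical caliper before each measurement maps to each
measurement being a fresh object with no carried-over state; blinding maps
to the distance being part of the log, not of anything shown to a simulated
grader. The full position history is retained — the study logged positions
without displaying them, and keeping every intermediate position is the
lossless choice.

`detect_fiducials()` is the automated stand-in for human landmark
identification: threshold, 26-connected components, intensity-weighted
centroids, components sorted by size then centroid. 26-connectivity was
chosen because metal components are compact blobs; the intensity weighting
makes centroids sub-voxel accurate (tests: within half a voxel on the
unblurred phantom).

## The grader simulator

Each simulated reading is

    diameter = truth × (1 + bias) + offset + Normal(0, sd_location)

with an independent draw per reading, and, for VR graders, a
Poisson(`refinement_rate`) refinement count. The design encodes the study's
independence assumptions: the two groups worked concurrently and
independently, graders were blinded to each other and to the displayed
value.

Calibrated defaults (`default_study_fixture()`):

* **VR bias** is multiplicative, matching the percentage framing of the
  published results: +6.74% at bead locations and +4.25% at pin locations,
  derived from the published group means. A single scalar bias is also
  supported (`bias_fraction`), and is what the parameter-recovery tests use.
* **Physical noise** is location-dependent, largest (1.4 mm SD) at
  location 3 — the oblique diameter inside the orbit, the location the
  physical graders could barely reach — and small (≈0.2 mm) at the easily
  accessible pins. The exact magnitudes are unpublished; these values were
  chosen once to qualitatively match the reported spread pattern and are
  not tuned thereafter.
* **VR noise** is small (0.08 mm SD) and location-independent ("results are
  consistent, irrespective of the location").
* **Refinement rate** is 1.5, the published mean correction count.
* **Grader offsets** default to 0 but are configurable — that is what lets
  tests make agreement and consistency ICC differ on demand.

Gaussian noise is the simplest model consistent with the ICC machinery;
the study reports variability patterns, not a noise distribution. Hand
tremor, controller tracking error and rendering transfer functions are not
modelled — the simulator reproduces the statistical structure the analysis
assumes, not the physics that generated it. Passing tests therefore show
the *analysis* is correct and the *conditions* are internally consistent;
they cannot validate the noise magnitudes against unpublished raw data.

## The statistics suite

**Summaries.** `summarize_locations()` pools graders × repetitions per world
per location; `summarize_groups()` aggregates into beads/pins/overall with
percent increases. The overall percent increase is the arithmetic mean of
the two group percentages — (6.74 + 4.25)/2 = 5.49 reproduces the published
headline figure, whereas pooling all nine locations would give ≈ 6.1 (the
six bead locations would dominate) and contradicts it.

**ICC.** `icc_twoway()` implements the two-way model with one observation
per cell (subjects = the 9 locations, raters = graders, cell = the mean
over the 3 repetitions — "single measures" reliability is the published
framing, and averaging repetitions keeps the layout two-way). Agreement
and consistency, single and average forms use the standard mean-square
formulas; confidence intervals use the exact F construction (consistency)
and the Satterthwaite-approximated F construction (agreement). Degenerate
inputs: a matrix with neither subject nor residual variance raises an
undefined-ICC error; exact perfect agreement returns ICC 1 with a collapsed
interval. The implementation is cross-checked in tests against a
brute-force ANOVA-by-summation oracle and against values frozen from an
independent reference implementation.

**Bland–Altman.** Per-location means of the two modalities are the pairs;
`d_bar`, the sample SD `s` of the differences, and limits `d_bar ± 1.96 s`.
The published formula statement is typographically incomplete; the limits
are implemented in the standard form, and the t-based confidence interval
of `d_bar` itself is reported separately rather than conflated with the
limits of agreement.

**Williams index.** Similarity kernel
`s(v_i, v_j) = 1 − (2/π) arccos(cos_sim(v_i, v_j))`, with the cosine
clamped to [−1, 1] before the arccosine. For rater j the index divides j's
mean similarity to the others by the others' mean mutual similarity,
*excluding j* from the denominator pairs — the classic construction, and the
one under which "index ≥ 1 means j agrees with the group at least as well
as the group agrees internally" is exactly true. At least three raters are
required.

**Effect sizes.** Welch's t (unequal variances), a two-sided variance-ratio
F-test with the larger variance in the numerator, and Cohen's d with pooled
SD, at a 1% significance level. Category bands follow the published usage:
large > 1.2, medium > 0.5, small > 0.01, with values ≤ 0.01 labelled
"negligible" (0.01 is an unconventional "small" floor, but it is the band
the results are reported in). Because it is ambiguous whether the published
tests pooled locations or ran per location, `compare_worlds()` returns
both: one row per location plus a pooled row. Note that under the
calibrated conditions the pooled contrast is diluted by the 25–42 mm spread
*between* locations, so per-location rows are the sensitive ones.

## Problem sizes and numerical choices

The default grid is 112³ voxels (70 mm cube) — the smallest isotropic grid
that holds the longest bead span (≈ 42 mm) plus the skull shell with
comfortable margin; tests use 96³. Law-of-large-numbers checks run at
10,000 repetitions with two graders; parameter recovery at 1,000
repetitions with the full seven-grader panel (63,000 readings), where the
delta-method standard error of the recovered percent increase is ≈ 0.01
percentage points. All simulation tests fix their seeds; every user-facing
entry point takes a seed and is bit-reproducible under it. Report output
rounds to 2 decimals for mm and percents; internal computation is full
precision.

## Known limitations

* Published reliability values (the ICC table) cannot be reproduced
  numerically — they depend on the unpublished raw readings. The package
  reproduces them *qualitatively* (near-perfect VR agreement under the
  calibrated conditions) and validates the machinery by oracle instead.
* One published cell is internally inconsistent (the pins minimum
  difference, printed 1.07, vs a per-row minimum of 0.65);
  `reproduce_reference_results()` computes extremes from rows and warns
  about the discrepancy.
* The bead percent increase computed from the 1-decimal per-location bead
  means is 6.77, not 6.74; the group-row precision issue above, not a
  model property.
* The phantom is geometric, not anatomical; the caliper has no tremor or
  tracking-error model; refinement counts are Poisson by assumption (only
  their mean is published).
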