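---
title: "Quantifying scaphocephaly severity from radial outline curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scaphocephaly severity from radial outline curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioquant)
```

## The measurement problem

Scaphocephaly — premature fusion of the sagittal suture — produces a long,
narrow skull, often with compensatory frontal bossing and occipital
bulging. The standard clinical measure, the cranial index (CI = biparietal
width / occipitofrontal length x 100), collapses the whole deformity into
one ratio and is blind to exactly those frontal and occipital compensations.

The method implemented here instead works from the *outline* of the skull.
Three external soft-tissue landmarks (the left porion and both exocanthia)
define a base plane; the cranial cross-section is taken on a plane 40 mm
above it; and the outline is unrolled into a radial curve: for each angle
around the section's centre of mass, the distance from the centre to the
outline. After normalization and phase alignment this "sinusoid" curve makes
the deformity legible — two peaks (occiput, forehead), two troughs (the
lateral sides), and the steepness of the transitions between them.

## The radial curve

`radial_profile()` casts rays from the area centroid (shoelace-moment
centroid of the enclosed region — deliberately not the vertex mean, which is
biased by non-uniform vertex spacing) at `n_samples` uniform angles and
records the outermost outline crossing per ray. The default is 360 samples
(1 degree), which resolves the threshold crossings used for the slope
variables with quantization below half a degree.

`normalize_curve()` divides by the circular mean radius. This is the only
normalization consistent with the dimensionless reference values the method
uses downstream (control sides about 0.85, occiput 1.1, forehead 1.15
straddling 1.0), and it makes the curve scale-invariant: a larger head with
the same shape yields the same curve. The mean radius in mm is retained for
provenance.

`align_curve()` rotates the phase origin to the occipital maximum — the
maximum within 90 degrees of the posterior direction, which is known from
the landmark frame (anterior axis = porion towards the exocanthion
midpoint; patient left = 90 degrees counter-clockwise from anterior seen
from above). After alignment every curve reads: occiput at 0, right trough
near pi/2, forehead at pi, left trough near 3pi/2, and the monotone
segments run descent-ascent-descent-ascent. Anchoring phase at the occiput
(rather than at the anterior landmark direction) is what fixes the printed
ordering of the four slope variables: first descent and second ascent
belong to the occiput, first ascent and second descent to the forehead.

All angles are radians on [0, 2pi). The slope variables below depend on
this unit choice, so the angular distance between threshold crossings is
reported alongside each slope, letting any other convention be recovered.

## Curve variables

`extract_features()` searches the four quadrants centred on the aligned
sector centres for the extrema: forehead maximum F, occiput maximum O,
right and left trough minima R and L (the anatomical search windows are a
package decision; the variables themselves are named anatomically). Derived
quantities follow exactly:

* width of skull (mean of both sides) = R/2 + L/2,
* difference occiput and sides = O − R/2 − L/2,
* difference forehead and sides = F − R/2 − L/2,
* difference forehead and occiput = |F − O| (the magnitude convention; a
  signed version is retained, since cohort summaries of the signed and
  absolute quantity differ).

`abruptness()` measures each monotone segment's steepness between the curve
heights 0.9 and 1.1: slope = ±0.2 divided by the angular distance between
the linearly interpolated crossings of the two levels. Descents (Do from
the occiput, Df from the forehead) are negative; ascents (Af to the
forehead, Ao to the occiput) positive. A segment that never reaches one of
the levels yields `NA` with a reason code — the package never extrapolates
a slope. When ripple produces several crossings of one level, the crossing
nearest that level's own end of the segment is used (1.1 nearest the peak,
0.9 nearest the trough), so the slope spans the full shoulder of the
transition and is robust to small oscillations.

## Three severity layers

**Cohort rank-sum score.** `ucsq_score()` ranks subjects on width (R + L;
the narrower, the higher the rank) and on summed peaks (F + O; the higher,
the higher the rank), ranks 1..N with average ranks on ties, and sums the
two ranks. The score spans 2..2N and its cohort mean is N + 1 by rank-sum
conservation — 22.00 for a cohort of 21, which is also a built-in
correctness check. The score is relative: it orders subjects within a
cohort and has no absolute meaning.

**Severity index.** `severity_index()` compares a subject with control
reference values — occiput 1.1, forehead 1.15, and width-of-skull 1.70
(2 x 0.85 for the two sides; note this "width of skull" is the *sum* R + L,
not the Table-style mean):

(O − 1.1) + (F − 1.15) + (1.70 − (R + L))

Classes: mild < 0.20, moderate in [0.20, 0.35), severe ≥ 0.35; both
boundaries belong to the more severe class per the published "≥" cut-offs.
Components are applied literally (they may be negative) and are reported
individually, because the two natural cohort aggregations — the formula on
cohort-mean extrema versus the mean of per-subject components — need not
agree and both are derivable from the outputs.

**Cranial indices.** `ci_traditional()` is width/length x 100 from maximum
extents; `ci_curve()` is the curve analogue 100 (R + L)/(F + O). Because
the curve lives at +40 mm rather than at the widest/longest level, the
curve CI systematically sits slightly below the traditional CI on elongated
heads; both are reported.

## Intracranial volume

`icv_from_mask()` integrates a binary intracranial mask slice-by-slice
(foreground area x slice spacing — the Cavalieri estimate; "extrapolation"
between slices is deliberately not done), with the voxel-count product as
an exact cross-check on axis-aligned grids. The analysis range (just above
the foramen magnum to just beneath the vertex) is the caller's choice of
`start_slice`/`end_slice`. `normative_band()` interpolates a user-supplied
age- and sex-specific normative table and classifies the volume into seven
SD bands; "At mean" uses |z| < 0.05 by default (the band exists in clinical
reporting but no tolerance is conventional, so it is configurable), and no
extrapolation outside the table's age range is allowed. The package ships
only a clearly synthetic normative generator (`make_normative_table()`, a
saturating growth curve with 7% SDs); real normative reference values must
be supplied by the user as CSV.

## Interrater statistics

`aggregate_visual()` averages each of the six visual items (width, length,
vertex height, frontal bossing, occipital bulging, temporal narrowing;
scores 0/1/2) over raters and sums the item means, giving the 0–12 overall
visual score. `icc_a_k()` implements ICC for a two-way random effects
model with absolute agreement on average measures, directly from the ANOVA
mean squares — (MS_subjects − MS_error) / (MS_subjects + (MS_raters −
MS_error)/n) — and is verified in the tests against a brute-force
sum-of-squares decomposition. `pearson_cor()` wraps `stats::cor.test()`.
Both carry the conventional interpretation scales (Landis–Koch for ICC;
negligible/low/moderate/high/very high for |r|). The published bin
descriptions overlap at their printed edges ("0.61 to 0.80", "0.81 to
1.00"); the package uses lower-inclusive bins with edges 0.20/0.40/0.60/
0.80 (ICC) and 0.30/0.50/0.70/0.90 (|r|), both configurable.

## The phantom generator

Every stage is testable without patient data through a parametric phantom:

r(theta) = r_ellipse(theta) + mean(r_ellipse) x [A_f g(theta; pi) +
A_o g(theta; 0) − A_t (g(theta; pi/2) + g(theta; −pi/2))]

an ellipse (anteroposterior by biparietal diameter) plus periodic Gaussian
bumps (default sd 0.5 rad — wide enough that the ascent/descent transitions
cross the 0.9/1.1 levels the way real scaphocephalic curves do) for frontal
bossing, occipital bulging and temporal narrowing, with optional i.i.d.
radial noise. Amplitudes scale the *mean* ellipse radius, so a dial value
is the bump height as a fraction of head size and feature locations are
analytically known. Head volumes are ellipsoid-like stacks of scaled
outlines with the exact analytic volume attached; rater tables mix a latent
truth with uniform noise at a controllable agreement level.

What the phantoms deliberately do not emulate: real cranial anatomy (no
skull thickness, no ears or orbits in the slice plane), CT intensities and
partial-volume effects, non-star-shaped outlines, or rater bias structure
beyond symmetric noise. Passing phantom tests therefore demonstrates the
correctness of the geometry, curve algebra and statistics — not clinical
validity on real CT data.

Default study-like conditions used in tests and in `scripts/acceptance.R`:
cohorts of 21 subjects (the clinical cohort size), curve resolution 360
samples, phantom outlines of 256 vertices (720 where a vertex must lie on
every ray for exactness checks), digital spheres of radius 50–60 mm at 1 mm
voxels, severity dial sweeps spanning CI roughly 60–80.

## Numerical choices and degenerate inputs

* Ray–edge intersection uses a half-open edge interval with a 1e-9
  tolerance so rays through a polygon vertex are caught exactly once; when
  the centre is not star-shaped the outermost crossing is taken and a
  warning count recorded.
* Marching squares (`grDevices::contourLines` at the 0.5 iso-level on a
  trilinearly resampled plane) extracts sub-voxel outlines from volumes;
  open contours (plane clipping the grid) are rejected, the largest closed
  loop wins, near-zero-area loops (tangent planes) are errors.
* The plane normal is oriented towards the head's foreground centre of
  mass when a volume is available — the cranium lies above the
  porion/exocanthion plane, which makes the choice anatomically forced.
* Whether "4 cm height" is measured along the landmark-plane normal or the
  scanner axis is ambiguous in the source descriptions; the package
  measures along the landmark-plane normal and documents this for users.
* Threshold-crossing ties (a sample exactly at 0.9/1.1) take the first
  touching sample; flat curves align by the anatomical frame with a
  warning and report all four slopes as undefined.
* Severity cut-offs, reference values, band tolerance and label bins are
  arguments with the published defaults, so deviations are explicit and
  visible in provenance.

## Known limitations

Only voxel-volume head representations are sliced (no triangle meshes);
outline inputs bypass the slicing entirely. The rank-sum score needs a
cohort and is not comparable across cohorts. Abruptness is undefined for
near-round heads by construction. The severity cut-offs were proposed from
a 21-patient cohort in the source literature and are exposed as
configurable parameters rather than clinical truth.
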