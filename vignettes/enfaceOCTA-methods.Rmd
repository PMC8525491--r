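---
title: "Methods: simulating and analyzing laser-induced retinal injury with en-face OCTA"
author: "enfaceOCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing laser-induced retinal injury with en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`enfaceOCTA` implements a combined orthogonal-OCT / OCT-angiography
analysis of laser-induced retinal injury in the mouse: a single
high-density intensity volume (nominally 1000 x 1000 A-scans at 1.4 um
lateral and 1.9 um axial pitch) is motion-registered, resliced into
B-scans and en-face C-scans, segmented into retinal surfaces, enhanced
into a vesselness volume, thresholded into a 3D angiogram, and summarized
into lesion morphometry, longitudinal dynamics, plexus-resolved perfusion
and an acute-versus-CNV call. Because no imaging data are deposited with
the study the package models, the package ships a first-class synthetic
volume generator whose ground truth (layer surfaces, per-plexus vessel
masks, per-lesion dimensions) is the oracle for every downstream test.

# The synthetic scene

## Anatomy and reflectivity

The retina is modelled as a stack of layers parallel to a smoothly
undulating inner limiting membrane (ILM): nerve-fibre/inner plexiform
layers, a dark inner nuclear layer, a brighter outer plexiform band, the
dark outer nuclear layer (ONL), thin bright external limiting membrane
(ELM) and inner/outer segment (IS/OS) lines, the bright retinal pigment
epithelium (RPE) band, and choroid. Reflectivities are free parameters
(no quantitative layer reflectivities are published for this system);
they were fixed once so that each band has the familiar qualitative OCT
appearance and the RPE is the brightest layer. The OPL/ONL boundary sits
85 um below the ILM and the RPE center 190 um below it, so the normal
OPL-to-RPE column is 105 um.

Three inner capillary plexuses (superficial SVP, intermediate IVP, deep
DVP) plus choroidal vessels are generated as meandering centerline paths
with per-vessel calibers (SVP arterioles up to ~22 um, IVP/DVP
capillaries 5-10 um, matching the calibers the angiography claims to
resolve) and rasterized into mutually disjoint binary masks in disjoint
depth bands.

## Speckle

Speckle is multiplicative with a contrast (coefficient of variation)
parameter, default 0.3. Its spatial statistics carry the physics that
this angiography method rests on: static tissue speckle is a *frozen*,
laterally correlated pattern (grain about one resolution cell, so
adjacent B-scans 1.4 um apart share most of it), while voxels inside
flowing vessels decorrelate voxel-by-voxel from erythrocyte motion.
Registration therefore has the dense stable texture real volumes have,
and vessels differ from tissue both in brightness and in speckle
statistics. Motion is integer-voxel per-B-scan translation drawn from a
bounded autoregressive walk (fast, zero-mean), recorded in the metadata
as the registration oracle. An optional decorrelation-tail artifact
(default 40% of vessel amplitude) is rendered in the DVP band beneath
superficial vessels as the shadow-rejection oracle, and large superficial
vessels cast mild (12%) shadows.

## Lesions

Lesion dimension time courses are calibrated to the packaged reference
table (`lesionDimensionTable()`): per condition and day it lists the mean
ONL disruption width, RPE disruption width, maximal OPL-RPE height and
ELM-IS/OS protrusion width, with per-cell CVs. With dispersion on, each
lesion's cell values are scaled by lognormal factors whose CV matches the
table cell (lognormal keeps dimensions positive and matches the CV
parameterization); with dispersion off the simulated dimensions equal the
table means exactly. Between printed days the means are interpolated
piecewise-linearly (no functional form is published); times before day 1
(the optional 1 h point) take the day-1 values.

Geometrically, a lesion is rendered so that each defined width is
unambiguous:

* a hyperreflective *fill* column runs from `190 um - height` below the
  ILM down to the RPE. Its lateral half-width is the ONL width through
  the nuclear layer and flares (or narrows) linearly to the RPE width at
  the RPE contact - the cylinder / hourglass / pyramid morphology of the
  acute lesion narrative. Edges are soft over 5 um with the half-
  amplitude point at the nominal radius;
* when the height exceeds the normal 105 um column, the excess becomes a
  swelling dome that displaces the ILM and OPL/ONL boundary upward (the
  inner retina rides on the swelling; the RPE never moves);
* the ELM and IS/OS lines are displaced 25 um upward into the ONL over
  the protrusion (PR) footprint;
* CNV lesions additionally carry an RPE rupture (radius 40 um times the
  scene's `dimScale`): the outer-retina bands and the choroid beneath the
  core are suppressed, which is the "void" appearance in sub-RPE slabs,
  and a mildly hyporeflective edema core appears in the fill from day 7;
* CNV lesions remove the centermost fraction (default 0.8) of
  deep/intermediate plexus vessel voxels inside the lesion cylinder at
  the timepoints where the condition's (unscaled) mean height reaches
  200 um - for the default grid, days 3 and 7 - reproducing the reported
  coupling between tall lesions and deep-plexus non-perfusion with
  reperfusion by day 14. Acute lesions never touch the vasculature.

## Desk-scale conventions

The generator keeps the acquisition pitches fixed and scales the grid
instead. A published-size CNV lesion is ~566 um wide, so a full 4-lesion
eye does not fit any desk-scale lateral grid; the stated placement margin
of one lesion diameter would demand >1.2 mm fields even for one lesion.
The package therefore (i) requires a quarter-diameter clearance between a
lesion's maximal footprint and the field edge, with 25%-dilated
footprints non-overlapping, and (ii) offers a scene-level `dimScale`
factor that shrinks lesion geometry only - the time-course structure, CV
structure and the non-perfusion schedule (keyed to the unscaled heights)
are untouched. The test suite uses full-size acute lesions (256 x 256
lateral), a half-scale CNV lesion (384 x 384) for morphometry, and
0.3-scale 4-lesion eyes (384 x 384) for the end-to-end classification
property; the acceptance checks on angiography run on a full 256 x 256 x
512 control cube. These sizes are the package's desk-scale protocol; the
full 1000 x 1000 grid is supported.

# Registration

Consecutive B-scans are aligned by FFT cross-correlation over integer
shifts (default +/-8 voxels per axis). Per-depth row means are removed
first: the layered background is laterally almost uniform, so the lateral
peak must be driven by vessels, surface undulation and the tissue speckle
pattern. Pairwise shifts are chained cumulatively and the smooth
component is removed with a low-order smoothing spline (about one degree
of freedom per 64 B-scans) before the negated fast component is applied.
A moving-median detrend (window ~31 scans) was evaluated first and
rejected: its stochastic error on the fast jitter itself approaches a
voxel, which violates the +/-1-voxel recovery target the simulator makes
testable. Registration is axial+lateral by default (`axialOnly` is
available); sub-voxel and non-rigid correction are out of scope.

# Surface segmentation

Per A-scan, after mild axial Gaussian smoothing: the ILM is the first
crossing of a 30% dynamic-range threshold; the RPE is the deepest strong
band - the deepest crossing of 65% of the windowed maximum within
[ILM+120, ILM+205] um, then the local peak just above it (a plain argmax
can lock onto bright lesion material, and the window stops above the
choroidal vessel layer); IS/OS and ELM are the brightest lines in windows
referenced to the RPE (IS/OS in [RPE-62, RPE-12], below which the RPE
shoulder leaks in); the OPL/ONL boundary is the strongest falling edge
above the ELM. Maps are median-smoothed (5x5) and depth-ordering is
enforced. Validity requires a bright RPE peak (70% of the field median)
at a plausible depth (>=165 um below the ILM): inside a rupture the
detector locks onto shallower lesion material and the position is flagged
invalid, which is exactly the rupture evidence the classifier uses.

# Vessel enhancement and angiogram segmentation

Enhancement is strictly en-face (2D per C-scan): the single-volume
contrast lives in the lateral structure, and per-slice processing
preserves axial localization. Stages, each logged: optional ILM
flattening (integer column shifts; C-scans of a curved retina otherwise
cut through bright layers and produce contour artifacts), per-slice
moving-median background subtraction (70 um window, well above the widest
vessel), local contrast normalization (84 um window with a volume-global
floor - a per-slice floor amplifies vessel-free slices to vessel level),
mild smoothing, and multiscale Hessian ridge (Frangi-type) enhancement at
scales matched to 5-40 um diameters with a fixed structure sensitivity
(the input is already normalized to unit scale). One
normalization+enhancement iteration is the default: a second pass
sharpens centerlines but thins wide superficial vessels and lowered mask
fidelity in calibration.

Segmentation is hysteresis thresholding per 60 um axial band. Thresholds
are fractions (0.35 high / 0.15 low) of the band's 99th-percentile
response rather than count quantiles: count quantiles cut into vessels
wherever vessels are not sparse (superficial-band recall was 0.27 at 0.94
precision before the change). Components smaller than 10 voxels (per
C-scan) are removed. Calibrated on control scenes, the shadow-rejected
angiogram reaches band Dice of about 0.8 (SVP), 0.7 (IVP, DVP) and 0.65
(choroid) against the generator masks.

Shadow rejection keeps the stated ratio rule - a voxel below the
superficial band is a removal candidate when its column's superficial
vesselness exceeds its own score by a factor (default 1.5) - but the
ratio alone cannot meet both sides of its own oracle (97% of tails
removed but 9% of true deep vessels lost). Candidates are therefore
removed when they sit in a connected component that satisfies the rule
almost everywhere (tail echoes do; crossing deep vessels only at the
crossing) or when their en-face neighbourhood correlates with the
superficial projection (tails are replicas; deep vessels carry their own
orientation). The superficial band is never altered and no voxel is ever
added.

# Morphometry and dynamics

The lesion-centered B-scan is landmarked as the midpoint of the
half-maximum run of mid-ONL hyperreflectivity along the slow axis (the
fill produces a plateau; an argmax would land anywhere on it, shortening
every chord measurement). On that B-scan, each width is the
half-amplitude crossing of a residual profile against the surround level
(outermost 15% of columns): mid-ONL band brightness for the ONL width,
brightness of the band just above the RPE for the RPE width (contiguous
invalid-RPE stretches, i.e. a rupture, count as disrupted), and upward
IS/OS displacement for the protrusion. Height is the vertical extent from
the first hyperreflective voxel below the (possibly displaced) OPL/ONL
boundary to the RPE. Profiles are anchored to a median-smoothed track of
the detected RPE - the only surface a lesion never displaces. Robustness
choices that matter: runs bridge sub-level stretches up to 35 um
(vessel-shadow dips inside a genuine disruption; the depth-based
protrusion profile is shadow-immune and uses a 7 um bridge), brightness
profiles are one-sided (shadow dips cannot extend a run), and the height
search keeps only the bright run contiguous with the deepest voxel (deep
plexus vessels graze the search top). On dispersion-off simulations the
measured dimensions land within ~2 um of the generator values at
full scale; IS/OS tracking through the bright CNV fill is the least
reliable element, so the protrusion width is most trustworthy for acute
lesions.

Dynamics follow the percent-change model: all measurements of a lesion
are normalized to its first value M0 (expansion positive), interval
changes D1 are differences as a percent of M0, and D2 = diff(D1). A
dimension reaches steady state at the earliest timepoint after which
every remaining |D1| stays within the significance threshold (default
5%). The onset must be followed by *at least two* sub-threshold
intervals: a single quiet final interval is not evidence of an asymptote.
This operationalization was chosen because it simultaneously reproduces
the reported acute protrusion onset at day 7 and the non-convergence of
all four CNV dimensions through day 21 (a rule admitting the penultimate
timepoint would call the CNV RPE trace steady at day 14 on the strength
of one 2.4% interval). Group statistics use the population standard
deviation (the source does not state the denominator) and pool a
condition's consistency as the unweighted mean of its (dimension, day)
cell CVs; zero-mean cells are excluded and flagged.

# Perfusion and classification

Vessel density is the positive-voxel fraction of an angiogram slab within
a lateral ROI. A timepoint is non-perfused below half (default) of the
baseline density - the pre-lesion scan when present, else a surround
annulus - and consecutive non-perfused timepoints merge into intervals
with the reperfusion day being the first recovery. The 0.5 drop fraction
separates the generator's scheduled removals (80%) from speckle-driven
density fluctuation at default noise. Classification is a pure rule over
four evidence fields: CNV if the RPE is ruptured or the sub-RPE slab
shows a void (core below half the surround), or if the maximal height
reached 200 um together with deep-plexus non-perfusion; acute if none of
the flags is raised; indeterminate otherwise. Laser dose accounting is
energy = power x time, reported at full precision and at the 3-decimal
rounding used in dose reporting.

# What passing tests do and do not show

The generator emulates layered reflectivity, correlated tissue speckle,
flow-decorrelated vessel speckle, motion jitter, shadows, projection
tails and calibrated lesion time courses. It does not emulate eye
curvature or reference-arm effects, sub-voxel or non-rigid motion,
phase/temporal decorrelation contrast, hemodynamics, bleeding, or
reflectivity pathology beyond the modelled phenotypes; lesion phenotypes
are smooth parametric shapes, so measurement accuracy on real, irregular
lesions will be worse than the ~2 um figures above. Passing tests
demonstrate that the implementations are correct and internally
consistent under the stated model, not that the algorithms meet the same
numbers on device data.

# Known limitations

* The half-amplitude width estimator assumes a plateau-like disruption
  profile; fragmented lesions would need a different rule.
* The ONL sampling band sits 55-85 um above the RPE, so miniature
  (heavily down-scaled) lesions shallower than ~130 um do not span it
  and report a zero ONL width; their RPE-contact width and height remain
  measurable.
* Shadow rejection depends on segmented surfaces; without a detectable
  ILM it refuses to run.
* The steady-state rule needs at least three timepoints and never
  declares an onset at the last interval.

# Reproducing the numbers

`scripts/acceptance.R --seed S --out results/acceptance.json` recomputes
the steady-state onset of the acute protrusion trace from the packaged
table. The acceptance tests in `tests/testthat/test-acceptance.R` rebuild
everything else from scratch: the pooled CVs, the steady-state calls, the
dose arithmetic, registration recovery, angiogram overlap on a full
desk-scale cube, capillary resolution, morphometry recovery, the
non-perfusion interval pattern, the 8-lesion end-to-end classification
and the dispersion parameter recovery.
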