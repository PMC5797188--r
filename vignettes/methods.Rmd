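---
title: "Methods: template construction, registration and quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template construction, registration and quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvreg)
```

# The problem

Gene-expression patterns imaged in different larval *Drosophila* CNS
preparations can only be compared after they are mapped into a common
reference space.  `larvreg` builds that reference: a population-based
standard brain template fused from the neuropil (NP) channels of a cohort
of good-quality scans, plus the machinery to register any new scan onto
it, carry its nerve-tract (NT) and gene-expression (GE) channels along,
score the registration automatically, and correct it with a handful of
manually placed landmarks when it fails.

All computation is in physical micrometres.  The acquisitions this
pipeline targets are strongly anisotropic (0.5 x 0.5 um in plane, 2 um
slices), so voxel indices are never used as distances; sphere radii,
control-grid spacings and error statistics are all micron quantities.
Coordinates are 0-based voxel indices with the physical origin at the
center of voxel (0,0,0); x is the fast in-plane axis, y the slow in-plane
(anterior-posterior / dorsal-ventral in the mounted preparations) axis,
and z the slice axis.

# Registration model

## Linear stage

Subject-to-template alignment runs six stages: (1) translation of the
intensity center of mass to the template's geometric center, flipping the
dorsal-ventral axis when the mass sits in the bottom half; (2) both
z-flip initializations are carried through the remaining linear stages
and the branch with the better final NP correlation wins (mounting can
flip the stack); (3) a similarity registration of signed-distance
transforms (SDT) of coarse brain masks, multi-started over in-plane
angles in +/-90 degrees, which recovers large X-Y rotations that defeat
intensity-based registration; (4) a fallback rule: if the SDT candidate's
NP correlation is below 0.4 an intensity-based similarity registration is
run, a candidate reaching 0.4 is selected, otherwise the better one is
kept and a registration-failure warning recorded; (5) a similarity
refinement on the NP channel with NCC; (6) composition.

The 0.4 threshold is evaluated as NCC of the NP channel under the
candidate transform on the full masked template domain.  The alternative
reading (thresholding the optimizer's own metric) would compare an
unbounded mutual-information value against a correlation-scaled constant;
a single commensurable scale is the only interpretation under which the
rule is meaningful.

Linear transforms are estimated with a deterministic Nelder-Mead simplex
over at most 12 parameters, on a fixed, seeded voxel subsample per
resolution level (2500 samples, 3 levels by default).  A stochastic
gradient scheme is the classical choice here, but for this parameter
count the simplex is equally accurate, fully reproducible, and has no
step-size schedule to tune; the deformable stage, where the parameter
count makes this impossible, keeps the stochastic scheme.  Similarity
transforms parameterize in-plane rotation only: out-of-plane rotations do
not occur in slide-mounted preparations (the z flip handles the one
discrete exception).

Reflections (determinant -1) are legitimate members of the pipeline (z
flip, dorsal-ventral flip), so resampling rejects only singular
transforms, not negative determinants.

## Deformable stage

The deformable model is a cubic B-spline free-form deformation with a 12
um control grid at the finest level, optimized over 5 levels with
control-grid spacings 96/48/24/12/12 um and a Gaussian image pyramid.
Levels are additive: each level optimizes a fresh control grid on top of
the accumulated displacement, which avoids repeated resampling of the
moving image while keeping every level's finite support.  The optimizer
is a stochastic gradient ascent on NCC with an analytically computed
gradient with respect to the control points and a decaying step length
`step0 * ((A+1)/(A+k))^0.602` (defaults `step0` = 1 um, `A` = 20, 300
iterations and 2048 intensity samples per level).  These counts are
exposed in the configuration and are not authoritative -- the published
framework adapts them per data set.

Two sampling modes mirror the two registration scenarios.  Pairwise
template-generation registrations sample uniformly over the whole image
domain (after histogram matching); subject-to-template registrations
sample a random isotropic cubic subregion of 20 um edge length inside the
template's brain mask at every iteration, a local similarity metric that
is robust to background structures and intensity inhomogeneity.  Whole-
image random sampling without a mask fails on this kind of data because
of abundant extra-brain structures; the mask is what makes the local
metric reliable, and the mode split is fixed accordingly.

## Semi-automatic correction

Failed registrations are corrected by a multi-metric variant: the cost
adds the mean Euclidean distance between transformed template guide
landmarks and their manually annotated subject positions.  Rather than
balancing the metric *values* -- whose scales are incommensurable -- the
metric *gradients* are balanced: at each level the landmark-term gradient
is rescaled so the two gradient magnitudes sit at a configured ratio
(default 1).  Two guide points (the terminal nerve entries) suffice for a
VNC-terminal failure, the six thoracic nerve entries for a thoracic
failure, eight for both.

# Template construction

The population-based (PB) scheme: all ordered pairs of the cohort are
registered (histogram matching, two-candidate z-flip affine, deformable),
giving dense fields `T_ij` on the grid of scan *i*.  Each member's mean
deformation field `T_i` -- the average of its deformations to all other
members, including its own zero deformation (`include_identity = TRUE`,
configurable; the published description is ambiguous on this term, and
including it weighs every subject equally in the average space) -- maps
it into the population average space.  Members are warped there with the
numerically inverted mean fields (damped fixed-point inversion, factor
0.6, up to 60 iterations, 0.1 um tolerance -- far below the voxel size;
the damping keeps the iteration convergent where field gradients approach
1) and fused voxelwise.

Median fusion is the default: with per-scan background streaks and
stray nerve strings, the voxelwise median suppresses what the mean blurs
into the background.  For even cohort sizes the median takes the lower of
the two middle values so 8-bit gray levels are preserved.  The brain mask
of the fused template comes from simple intensity thresholding -- the
median-fused background is homogeneous enough that no morphology is
needed -- whereas subject masks are computed by Otsu binarization at half
resolution followed by a 2 um morphological opening (removing fragments below the
2-8 um landmark-structure scale while keeping nerve-entry protrusions of
that scale) and
largest-component selection.  The average-space sampling grid is the grid
of the first cohort scan; nothing in the construction depends on which
member is first beyond that grid choice.

The NT template (and any GE mapping) is produced by warping those
channels with the transforms estimated on the NP channel; secondary
channels are never registered themselves.

# Automatic quality assessment

Two local indicators, calibrated once at template-build time and stored
in the template package:

* **VI** (VNC terminal): mutual information between template and
  registered NP in 10 um spheres at the two terminal nerve-entry
  anchors, expressed in percent of the calibration cohort's maximum (the
  best-registered terminal defines 100%), reduced over the two anchors by
  the minimum.
* **TI** (thoracic nerves): per anchor, `M` is regional MI in a 15 um
  sphere (percent of calibration max) and `S` is a confidence score from
  the Eulerian (Almansi) strain magnitude `||(I - (F F^T)^{-1}) / 2||_F`
  of the deformation field in a 35 um sphere.  Strain is normalized by
  the calibration median and (unscaled) MAD, its 95th percentile taken,
  and inverted onto a percent scale anchored to the calibration cohort:
  `S = 100 (1 - clip(z95 / (2.5 z95max), 0, 1))` with `z95max` the worst
  per-anchor value seen during calibration, so 50% confidence sits at
  1.25 times the worst calibrated strain.  The published description
  fixes the normalization (median/MAD, 95th percentile) but not the
  direction or the end points of the percent scale; this mapping is the
  package's choice and is the one place the S score has a free constant.
  `TI = M * S / 100`, reduced over the six anchors by the minimum -- a
  single failed nerve must flag the scan.

A scan is flagged for manual correction iff VI or TI falls strictly below
the 50% threshold (exactly 50 is accepted).  MAD uses no consistency
factor; a zero MAD falls back to the IQR, then to 1.  Strain is
calibrated per cohort, not per scan; per-scan scaling would make S blind
to globally distorted registrations.

# The phantom world

All tests run against a seeded synthetic cohort, not the original
multi-gigabyte stacks.  The canonical phantom is a geometric larval CNS
-- two ellipsoidal brain lobes with dorsal vertical-lobe bulges, a
tapering ventral nerve cord with three pairs of thoracic protrusions and
abdominal nerve-root bumps -- rendered at 128 x 96 x 24 voxels with the
real anisotropy (0.5, 0.5, 2 um), i.e. about 1/10 linear scale in plane.
The NP channel carries a fixed pseudo-random interior texture (so NCC has
gradients inside the tissue), the NT channel thin tract curves, the GE
channel sparse blobs.  Noise is Gaussian read noise (sd 3 gray levels)
plus an intensity-dependent term -- values chosen once to keep
registration solvable but non-trivial; they are not fitted to any
criterion.  QA sphere radii stay at their true 10/15/35 um values; only
the anatomy is smaller.

Phantoms are rendered through a random smooth B-spline warp of stated
peak amplitude (the 5-10 um range used throughout mirrors the
deformation scale of good-quality data).  The ground-truth transform is
recorded; subject-space landmarks are obtained by fixed-point inversion
and are consistent with the recorded transform to 1e-6 um.  Corruption
modes emulate the observed failure categories: a smoothly windowed 15 um
displacement of the weakly stained VNC terminal, a concentrated
negative-Jacobian thoracic fold (12 um, the one deliberate violation of
invertibility), attenuated staining, z truncation, and a missing NP
channel.

Where a test needs "the outcome of a failed automatic registration"
without paying for an optimizer run, `simulate_registration()` constructs
it: the exact inverse ground-truth field for clean scans; the inverse of
the smooth component only for the VNC-shift failure (an automatic run
that missed the locally displaced terminal -- precisely the mismatch VI
detects); and, for the thoracic failure, the smooth inverse with the fold
displacement added directly in template space (a distorted registration
-- what the strain score detects; the folded ground truth itself has no
well-defined inverse).  The correction benchmark initializes from the
smooth-only inverse of shift-type failures; anatomically folded phantoms
are detection cases only, since a transform that matches folded content
must itself fold and the strain score rightly keeps flagging it.  A green phantom suite therefore establishes that the method
recovers smooth warps of the stated amplitude on well-staining anatomy
and that the indicators separate these specific failure modes; it does
not establish performance on real staining variation, mounting damage, or
anatomy outside the geometric model.

# Numerical choices and degenerate inputs

* Interpolation: trilinear for intensities (tricubic available), nearest
  for masks; out-of-domain voxels take background 0.
* Histogram matching: monotone piecewise-linear mapping through 7
  interior percentile match points plus the range endpoints; constant
  images map to themselves with a warning.
* Robust rescale percentiles: 1 / 99.8 -- the upper cut saturates tile
  acquisition artifacts without flattening bright neuropil.
* Mattes MI: 32 bins (conventional for 8-bit microscopy), cubic B-spline
  Parzen window, plug-in estimate in nats; constant channels give 0.
* Regional MI spheres must hold at least 50 voxels, otherwise the
  geometry is too coarse for the statistic and an error is raised.
* Even-count medians take the lower middle value.  Sample (n-1) standard
  deviations everywhere; on the shipped reference tables the printed
  one-decimal values round identically under either convention.
* Degenerate deformation gradients (|det F| <= 1e-6) get the field's
  largest finite strain magnitude and a warning, so folds dominate the
  95th percentile instead of producing NaNs.
* Dense-field inversion is only valid for invertible fields; applied to a
  deliberate fold it yields large gradients, which is the behaviour the
  strain indicator relies on.

# Known limitations

* Recovery of arbitrary 3D rotations is out of scope; only in-plane
  rotations plus the discrete z flip are modelled, as in the data this
  targets.
* The additive multi-level B-spline stack is not a single-grid B-spline;
  `register_bspline()` returns the stack (finest level 12 um).  Its
  displacement, not its coefficients, is the contract.
* The linear optimizer evaluates a subsample, so metric values carry
  sampling noise of order 1e-3; monotone-improvement guards use a 1e-6
  slack and the pipeline keeps the better of pre/post refinement.
* TIFF support is baseline (uncompressed grayscale, 8-bit or float32,
  ImageJ-style slice spacing); LSM and Bio-Formats metadata are not
  parsed.
* The phantom's intra-rater "annotation" is exact by construction;
  nothing in the phantom world reproduces human annotation error, which
  is why the shipped gold-standard deviation table is data, not
  simulation.
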