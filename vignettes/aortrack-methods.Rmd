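---
title: "Measuring segmented aortas by minimal-cross-section tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring segmented aortas by minimal-cross-section tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Clinical surveillance of aortic aneurysms tracks the maximal diameter of
the aorta measured in the plane perpendicular to the vessel's course: among
all planes through a point of the lumen, the one with the smallest
cross-sectional area. An oblique plane always overestimates the diameter,
so the minimal-area plane is the clinically meaningful one. `aortrack`
computes this measurement densely along a segmented 3D aorta — a binary
voxel mask — rather than at a handful of hand-picked locations.

The tracker mimics the manual procedure. It is seeded at the inferior end
of the mask (the aorta at the diaphragm), where the vessel can be assumed
to run nearly parallel to the inferior–superior axis; the centers of mass
of the two most-inferior axial slices with at least `min_area_mm2` of
foreground define the starting points and direction. Each subsequent step
extrapolates along the two previous centerline points, searches a ±30°
cone of plane orientations for the minimal connected cross-section
("wobbling"), re-centers on that section's center of mass, and records
area and maximal/minimal Feret diameters. No smoothing or spline fitting
is applied to the centerline: the output of interest is the diameter
profile, not the curve's exact shape.

### Assumptions

* The mask is a single vessel without loops; side branches may be present
  and are handled by the connected-region restriction (and may cause the
  documented branch-exit failure mode, below).
* The inferior end of the vessel is approximately vertical and is where
  tracking starts. The inferior–superior axis must be identifiable from
  the NIfTI header, or supplied explicitly for STL input.
* World coordinates are millimetres; voxel indices are 0-based with the
  voxel-center convention, so geometry is unambiguous under anisotropic
  spacing.

## Tunable parameters

All parameters live in `tracking_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `step_mm` | min voxel spacing | mm | extrapolation step; sub-voxel steps give a dense profile |
| `wobble_max_deg` | 30 | deg | half-angle of the orientation search cone |
| `wobble_coarse_deg` / `wobble_fine_deg` | 3 / 0.5 | deg | coarse grid and local refinement resolution |
| `pitch_mm` | min spacing / 2 | mm | in-plane resampling pixel; bounds diameter discretization error to below clinical 0.1 mm reporting only in combination with the Feret convention below |
| `min_area_mm2` | 10 | mm² | smaller connected sections terminate tracking; below any plausible aortic lumen, so segmentation spurs are not chased |
| `half_fov_floor/factor/max` | 20 / 3 / 60 | mm | plane field of view adapts to 3× the previous maximal radius |
| `stall_window` | 5 | steps | consecutive degenerate/reversing steps before `stalled` |
| `lookahead_mm` | 30 | mm | probe distance used to classify terminations |
| `progress_min_frac` / `move_max_frac` | 0.2 / 3 | ×`step_mm` | per-step sanity band on the re-centered step |

## Numerical choices

**Sub-pixel wobble objective.** The cross-section area of a tube tilted by
θ grows as 1/cos θ — quadratically near the optimum. At 0.5° this is a
few hundredths of a square millimetre, far below the quantization of a
thresholded pixel count. The wobble therefore minimizes a sub-pixel area
estimate: the sum of the trilinearly interpolated mask values over the
connected component dilated by one voxel's worth of pixels. This varies
smoothly with orientation and lets the search resolve the optimum at its
0.5° resolution. Reported cross-sections still use the pixel-count area,
which is the defined measurement. Ties in the search are broken toward the
smallest tilt from the travel direction, then lexicographically in the two
tilt angles, making the tracker fully deterministic.

**Multiresolution search.** The coarse stage evaluates candidates at twice
the pitch and the fine stage at full pitch (re-evaluating the coarse
argmin at full pitch so the two stages compare like with like). The fine
grid spans ±(coarse/2 + fine) around the argmin, which covers the maximal
distance between the true optimum and the coarse grid point.

**Inferior extension.** The inferior face of a segmentation is where the
imaging volume cut the vessel, not an anatomical end. Near such an open
face the minimal-area search finds obliquely *truncated* cuts whose center
of mass regresses or lurches, which would corrupt the first steps. Before
tracking, the most-inferior foreground slice is replicated 25 mm downward —
a virtual continuation of the vessel through the diaphragm — and steps are
recorded only once the centerline crosses the original boundary.

**Termination classification.** When forward progress collapses (below
0.2·step) or the center jumps (beyond 3·step), or the extrapolated point
leaves the mask, the tracker probes up to `lookahead_mm` ahead along the
direction of the last ten steps (the instantaneous direction can be
corrupted by the very event being classified): lumen continuing without a
gap means the tracker is stuck (tolerated briefly, then `stalled`); a gap
followed by more mask is an unsegmented pocket (`lost_lumen`); a gap with
nothing beyond is the end of the vessel (`completed`, or `exited_mask` if
the recent lumen was already degenerate). A trace ending `completed` or
`exited_mask` whose area series collapsed by more than 60% within a
10-step window without recovering is re-labelled `branch_exit_suspected`;
the flag is advisory and no correction is attempted.

**Feret diameters.** The maximal diameter is the largest distance between
boundary-pixel centers, computed exactly via the convex hull (interior
pixels cannot be hull vertices, so this equals the all-pairs maximum). The
minimal width uses rotating calipers over hull edges, which is exact for
convex polygons. Measuring between pixel centers matches an inner-edge
measurement convention. What the clinical tools' "maximum diameter" means
for strongly concave lumens is not standardized; the Feret diameter is
this package's definition.

**Phantom voxelization.** Phantom masks set a voxel to foreground when its
center lies strictly inside the analytic solid. The sampling lattice is
offset from the solid by 0.37 voxel: integer-radius solids aligned with
the lattice otherwise place lattice points exactly on the surface, and
strict inside-testing then produces atypically small sections (a
degenerate boundary case no real acquisition exhibits).

## What the phantoms emulate — and what they do not

The generator produces tubes with exactly known centerlines and diameter
functions at the 1 mm isotropic spacing typical of 3D SSFP acquisitions:
straight and tilted cylinders (plane sampling and wobble correctness), an
elliptical tube (max/min diameter), a half-torus and a candy-cane arch
(curved-vessel traversal: vertical descending limb, half-torus arch,
short ascending limb), a candy-cane with an arch branch, and a tube with
an interior spherical cavity (unsegmented lumen pockets). Optional seeded
boundary jitter perturbs the implicit-surface threshold per voxel,
emulating rough manual segmentation.

The branched phantom deserves a note. A small side branch on a uniform,
gently curving trunk does *not* capture a center-of-mass tracker: the
centroid pull of a branch with 0.4× the trunk radius is area-weighted at
about 14% and trunk re-centering wins at every step. Clinically, trackers
escape into arch vessels where the branch takes off and the trunk narrows
into the isthmus — common in congenital aortopathy. The branched phantom
therefore tapers the trunk smoothly (default factor 0.55 over a 25°
transition ending at the ostium) with the branch continuing along the
local direction of travel; under these conditions the tracker genuinely
redirects into the branch and the area-collapse flag fires. Passing this
scenario shows the failure mode is reproduced under conditions that
provoke it — it does not quantify how often it would occur across real
anatomies.

Phantoms do not emulate MR intensity, bias fields, partial-volume
intensity gradients, motion, or multi-vessel anatomy; truth functions are
declared valid only two tube radii away from the open ends, where cap
effects vanish. Agreement with analytic truth on phantoms bounds
geometric/discretization error only; it says nothing about segmentation
quality, which dominates error on real data.

## Agreement statistics

`icc_two_way_single()` implements the single-measure two-way
random-effects intraclass correlation with absolute agreement, ICC(2,1) —
the variant appropriate when two measurement methods are meant to be
interchangeable. It is computed from the two-way ANOVA mean squares
(subjects × raters), with Shrout–Fleiss F-based 95% confidence bounds
using a Satterthwaite degrees-of-freedom approximation, and the F test of
MSR/MSE for the p-value. Confidence-interval conventions differ between
implementations; the bounds here follow the classical Shrout–Fleiss
formulas. Missing reference measures are dropped pairwise per site, so
per-site N varies, as is typical when some anatomic locations cannot be
measured clinically. The spike filter excludes steps whose maximal
diameter exceeds a 15-step rolling median by more than 50% (planes
escaping into head-and-neck vessels produce such spikes); flagged steps
are excluded from the peak search but kept in the profile, where they act
as anatomical landmarks.

## Problem sizes used by the test-suite

The tests and the acceptance script run on: cylinders of radius 8/10/15 mm
and length 80 mm at 1 mm spacing and 0.5 mm pitch; a candy-cane arch of
tube radius 12 mm and arch radius 40 mm (≈216 mm analytic centerline); 200
seeded random regions for the Feret oracles; and 1000 ICC replicates at
n = 50. These sizes keep a full run in the minutes range on one CPU while
leaving every measured quantity well above its discretization floor.

## Known limitations

* Tracking follows a single vessel; bifurcation handling and automatic
  correction of branch exits are out of scope (the flag is advisory).
* The initialization assumes a near-vertical vessel at the inferior
  volume edge; a mask whose inferior end is strongly oblique would need a
  different seeding strategy.
* Diameters are measured on the binary mask: no sub-voxel surface fit is
  attempted beyond trilinear interpolation, and circumference is not
  computed.
* The ICC's confidence interval assumes the two-way random-effects model;
  with n < 5 pairs the bounds are wide and the estimate unstable.
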