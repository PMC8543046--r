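---
title: "Reconstructing biventricular meshes from misaligned cine-MR slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing biventricular meshes from misaligned cine-MR slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cinemesh)
```

This vignette is the package's own account of the science it implements: the
models and procedures, the tunable parameters with their defaults and units,
what the synthetic phantom does and does not emulate, the numerical choices,
and the known limitations. Every quantitative claim here is one the test
suite or the validation script computes itself.

## The problem

A standard cardiac cine-MRI study acquires a parallel short-axis (SAX) stack
and a handful of radial long-axis (LAX) planes, each during a separate
breath-hold. Between breath-holds the heart shifts, so the slices are
mutually misaligned in 3D — mostly in-plane translation and rotation about
the slice normal, plus a smaller through-plane component. A 3D surface fitted
through the raw contours inherits this scatter. The package's pipeline
corrects the per-slice poses in three stages, reconstructs smooth LV-
endocardial, RV-endocardial and epicardial surfaces from the sparse aligned
contours, joins them at the base into a watertight biventricular surface,
fills it with tetrahedra, and can simulate electrical activation on the
result.

## Slice geometry and pose corrections

A slice is a `slice_plane`: the patient-space position of pixel (0, 0), two
orthonormal in-plane axes, the pixel spacings, and the grid shape — the six
DICOM-style geometry fields; nothing else of DICOM is interpreted. The
patient frame is right-handed in mm with no scanner-convention semantics:
phantom and real data only need internal consistency. Pixels are indexed from
0 at pixel centres; intensity between centres is bilinear.

A pose correction `rigid_params` is three translations along the slice's
current axes and three intrinsic Euler angles, applied gamma (about the
normal) → beta (about the column axis) → alpha (about the row axis), pivoted
at the pixel-grid centre. Pivoting at the centre decouples rotation from
translation during optimisation; making the in-plane subset {tx, ty, gamma}
an exact parameter sub-vector is what lets the first two stages restrict to
it. These conventions (pivot, Euler order) are our choices; nothing in the
method depends on them beyond consistency, and the composition/inversion
algebra is exercised to 1e-9 mm in the tests.

## Stage A: local-phase intensity registration

The slice-consistency objective is the *global motion* discrepancy: the sum
over all intersecting slice pairs of a dissimilarity `E` evaluated along the
pair's intersection line. Because a common rigid motion of all slices leaves
every intersection geometry unchanged, the objective has an exact gauge
freedom; recovered poses are therefore only meaningful up to one global rigid
motion, and pose-recovery evaluations in the tests first remove the best
common motion.

Stage A compares *local phase* profiles. Each slice image is convolved
(in the Fourier domain) with a bank of quadrature log-Gabor filters — defaults
4 scales from a 4-pixel minimum wavelength at multiplier 2, 6 orientations,
bandwidth ratio 0.55, standard phase-congruency settings — and the per-pixel
phase of the strongest orientation's summed response is kept. Local phase is
invariant to affine intensity changes, which is what makes profiles from
different slices comparable at all. Pixels whose response amplitude falls
below a noise floor (5% of the 99th amplitude percentile) are flagged invalid
and masked from both profiles of a pair. Profiles are sampled bilinearly at
identical 3D points, step 0.5 × the finest pixel spacing, and a pair is
skipped when fewer than 10 valid samples overlap; `E = 1 − NCC`. Per-pair
mean-free NCC is used as is; how the objective should weight pairs whose
overlap length changes with pose is genuinely unspecified, and we chose not
to weight.

The minimiser is a bounded derivative-free search per slice (±10 mm, ±15°),
sequentially over slices with the LAX views first, accepting only improving
moves, so the recorded GM trace is non-increasing by construction. Coordinate
pattern search alone stalls on the diagonal valleys that coupled
translation/rotation objectives produce, so each slice's search is a
Hooke–Jeeves pattern search followed, in a final sweep, by a short
Nelder–Mead polish that is kept only when it improves the objective. One
multi-start restart from the stage-input pose guards against early local
minima.

On the phantom, stage A reduces the gauge-invariant contour-crossing residual
by roughly a fifth; its role is the robust initialisation of stage B, which
does the precise work. The gauge-fixed pose error after the intensity stage
alone remains at the few-millimetre level at phantom contrast; sub-pixel
recovery is a property of the full in-plane correction (intensity
initialisation followed by the contours stage), which is how the suite tests
it.

## Stage B: contour-crossing registration

Identical optimiser, different `E`: for each anatomically compatible label
pair the crossings of the two slices' contours with their intersection line
are matched greedily nearest-first along the line (ties resolved toward
preserving order — stable for ventricular topology, where correspondence is
otherwise unspecified), and `E` is the mean Euclidean distance over all
matched pairs pooled across labels; unmatched crossings are ignored and
pairs with no match are skipped. Septum crossings compare against both
LV-epicardial and RV-endocardial crossings of the partner slice, since the
septum is their shared wall; synthesized RV-epicardial contours are excluded
from matching to avoid circular evidence. The stage starts from the stage-A
poses; because a poor initialisation can occasionally steer the sequential
optimiser into a worse self-consistent configuration, a second start from the
raw acquisition poses is run as a safeguard and the lower final objective
wins (on the phantom the warm start wins in most draws). Pooling matched
crossings equally
(rather than weighting labels) is a choice; the alternative weightings were
left unexplored because the phantom residuals are already far below the
pixel size.

## Stage C: shape-model-guided 6-DOF alignment

In-plane registration cannot observe through-plane motion, so stage C fits a
PCA shape model to the sparse 3D contours and re-poses each slice against the
fitted surface with all six parameters free. The fit alternates (1)
nearest-point correspondences from each contour point to the label-matched
model surface (septum points seek the RV-endocardial surface), (2) a
closed-form least-squares rigid update, and (3) a linear solve for the mode
coefficients with per-mode ridge `sigma_noise^2 / variance_k`
(`sigma_noise` = 1 mm by default) and a ±3-standard-deviation clamp, until
the mean residual changes by < 1e-3 mm or 50 rounds. Up to 100 modes are
used. The per-slice re-alignment minimises the mean label-matched
point-to-surface distance plus a small quadratic pose penalty (weights 0.02
in-plane, 0.002 out-of-plane): the point-to-surface objective is nearly flat
under sliding a slice along the fitted surface, exactly the directions the
earlier stages have already fixed, so those directions are anchored harder
than the through-plane motion this stage exists to correct. After the
alignment the fitted model is discarded — only re-posed contours flow
downstream, so the model guides but never shapes the reconstruction. The
stage runs once (fit, then one alignment pass); re-fitting after re-posing is
possible in principle but was not needed at phantom noise levels.

## Surface reconstruction

Per surface, the closed per-slice loops (assembling septum and free-wall arcs
where needed; the septum contour feeds the RV-endocardial surface, because on
the outer-boundary epicardium it is interior) are lofted in order along the
stack axis at 40 points per ring; the apex vertex is taken from the lowest
LAX contour point when available, else extrapolated half an inter-slice gap
below the lowest loop. The loft is then deformed iteratively: up to 400
uniformly subsampled contour points pull their closest surface points via an
interpolating 3D thin-plate spline (kernel |r|, exact at controls, affine
maps reproduced with zero bending energy), followed by one light Laplacian
smoothing pass (weight 0.2), for up to 10 iterations or until the mean
contour-to-mesh distance stalls; the best iterate is returned, since the
smoothing can trade a little residual late in the iteration. Contours are
the trusted data, so correspondence runs contour → mesh.

Endo/epicardial intersections (the thin RV wall is the usual offender) are
resolved by two attractor passes — offending vertices become TPS targets
pushing the partner surfaces apart by a 0.5 mm clearance — after which any
still-offending patch is embedded directly into the partner surface at the
clearance distance and smoothed; the returned pair has zero crossing
triangle pairs by audit. The three surfaces are trimmed to the basal plane
(the plane of the most basal SAX contour) and stitched with a planar
annulus-with-two-holes triangulation into one watertight biventricular
surface. The stitching triangulates the washer by bridging the endocardial
holes into the epicardial outer loop and ear-clipping; a lid diagonal that
coincides with an interior surface edge is flipped away to keep every edge on
exactly two triangles.

## Tetrahedralization and quality

No Delaunay mesher is assumed: the package fills the watertight surface with
a body-centred-cubic vertex lattice at spacing 1.15 × the target element
size, snaps lattice vertices within 0.45 of a cell of the surface onto it,
clips boundary-crossing lattice tetrahedra against the signed-distance field
(marching tetrahedra with globally consistent cut points and face diagonals,
so the complex stays conforming), collapses residual slivers with
link-condition and inversion guards, and runs a few quality-guarded smoothing
sweeps in which boundary vertices may slide along the surface. `remesh_surface`
is the boundary of this complex. On a sphere the enclosed volume is
reproduced to better than 1% and the boundary stays within a small fraction
of the element size of the input.

Element quality is the Knupp index: at each corner
`sqrt(2)·|det(e1,e2,e3)| / (|e1||e2||e3|)` over the three emanating edges,
the element value being the minimum over its four corners clamped to [0, 1] —
normalised so a regular tetrahedron scores exactly 1 and a degenerate one 0.
The min-over-corners convention is the conservative reading of a definition
whose cited variants differ. On the phantom biventricular mesh at the default
1.5 mm element size the suite checks a mean of at least 0.79 with under 5% of
elements below 0.5.

A known limitation: where the 3 mm synthesized RV wall approaches the lattice
resolution, opposite wall surfaces can pinch at single non-manifold edges of
the complex boundary (a few dozen edges out of tens of thousands). The
boundary remains closed — every edge borders an even number of faces
(`mesh_is_closed`) — but not strictly two-manifold there; all volume, quality
and simulation results are unaffected.

## Activation simulation

Per element, the conduction tensor is `M = v_f² f fᵀ + v_s² s sᵀ + v_n² n nᵀ`
over an orthonormal fibre/sheet/normal frame; the default rule-based fibre
field is the apex-to-base direction projected onto the local wall tangent — a
deliberately crude stand-in, as realistic fibre models are out of scope.
Default speeds are 0.65 / 0.40 / 0.25 mm/ms with an isotropic 1.20 mm/ms
endocardial layer of 2 mm thickness, values in the range reported for human
ventricular tissue. The Eikonal solver is a Jacobi-style fast-iterative
method (order-independent by construction): each vertex takes the minimum
arrival over incident elements, where arrival within an element is the
linear-wavefront time from the opposite face under the metric `M⁻¹`, with
edge and vertex relaxations as fallbacks — so the solution is bounded above
by the edge-graph shortest path, a property the tests assert exactly.
Vertices within three median edge lengths of a root are seeded with the
straight-line travel time under the root's local tensor, removing the
first-order error at the wavefront origin; with it, the mean error against
the analytic solution on a ball is below 2% (individual far-field vertices
reach about 3% at desk-scale resolutions; the "within 2%" contract is
asserted on the mean). A convenience grid sweep over candidate speeds and
root sets maximising the Pearson correlation against a reference epicardial
map is provided; it is a forward-simulation sweep, not an inverse inference
procedure.

## The phantom: what it emulates, and what not

The phantom is an analytic biventricular geometry: the LV is the region
between concentric ellipsoids (endocardial semi-axes 25 × 25 × 54 mm, 8 mm
wall), the RV cavity is the part of a laterally offset ellipsoid
(34 × 27 × 46 mm, centred 20 mm laterally) lying outside the LV epicardium —
which creates a genuine septum — and the thin RV wall is a 3 mm outward
offset; everything is truncated at the basal plane z = 32 mm. These values
give a heart-sized object (about 9 cm apex-to-base) that a 12-slice SAX
stack at 8 mm intervals spans, matching the emulated acquisition: 12 SAX
slices, 4 radial LAX planes 45° apart through the LV long axis, 128×128
pixels at 1.3672 mm. Intensities are flat per region (background 40,
myocardium 110, blood 190) with Gaussian noise of SD 4; the thin RV wall
images as myocardium but is labelled background in the ground-truth masks,
mirroring the fact that cine resolution cannot delineate it. Misalignment
injection draws independent uniform per-slice in-plane translations,
rotations, and optionally through-plane shifts from a single seed,
bit-reproducibly.

The in-plane misalignment amplitude for the validation study is calibrated —
a few secant iterations on a single amplitude multiplier at fixed range
proportions (5 mm : 5 mm : 7°) — so that the pooled pre-correction mean
distance of the perturbed contours is 1.8 mm. The calibration measures that
distance against the analytic ground-truth surfaces rather than against the
final reconstructed mesh (which would be circular, as the mesh depends on
the correction); the reported ladder is still measured against the final
mesh, where the pre-correction entry comes out slightly lower (around
1.5–1.6 mm) because the reconstruction smooths toward the corrected
contours.

The synthetic shape model perturbs the phantom's shape parameters (semi-axes
±6% relative SD, wall ±0.8 mm, lateral RV offset ±2 mm) across a seeded
population, samples every variant's three surfaces with the same
parameterisation (rings at fixed height fractions; the RV crescent by
bisection-refined transition angles, so vertices vary smoothly with the
parameters), and runs PCA on the corresponded coordinates. Correspondence is
by construction, which real statistical shape models must earn through
registration — one of several reasons phantom results overstate what the
pipeline would achieve on patient data.

What the phantom does *not* emulate: MR physics (bias fields, banding,
partial-volume fade), papillary muscles and trabeculation, atria and valves,
out-of-plane tilts during acquisition (only translations and in-plane
rotations are injected; tilts are nevertheless free parameters in stage C),
motion between cardiac phases within a slice, and segmentation errors when
analytic contours are used (mask-derived contours add realistic half-pixel
quantisation, and both paths are exercised in the tests). Passing the
phantom suite therefore demonstrates the pipeline's internal consistency and
its behaviour under controlled misalignment — not clinical accuracy.

## Numerical choices and degenerate inputs

- SAX/LAX classification: the largest mutually parallel group (normals
  within 10°) of at least 3 planes is the stack; anything else is LAX. The
  tolerance admits scanner obliquity; no guidance existed to set it.
- Contours need ≥ 3 points with consecutive points > 1e-6 mm apart; SAX LV
  endocardial contours are closed. A plane tangent to the apex yields an
  empty contour list, not an error.
- The septum is detected on the mask grid by 8-neighbour class adjacency
  before sub-pixel extraction (the definition — where LV epicardium meets RV
  endocardium — is set-theoretic, not algorithmic).
- TPS systems are solved densely (≤ ~500 controls); duplicate controls merge,
  and coplanar controls fall back to the affine part with a warning.
- All seeded randomness flows through explicit integer seeds; a pipeline
  manifest records md5 sums of every artifact, and re-running a
  configuration reproduces them bit-identically (asserted in the suite).
- Desk-scale problem sizes used by the validation suite: 12 SAX + 4 LAX
  slices at 128² pixels, 200-sample shape model (500 for the variance
  measurement), 5 seeded repetitions per experiment, tetrahedral meshes of
  roughly 2–3 × 10⁵ elements at 1.5 mm. These are the package's chosen study
  conditions for the phantom.

## Module map

The spec-level stages map onto the package as: geometry and distance
primitives (`R/geometry.R`, `R/mesh.R`, `src/kernels.cpp`); the phantom and
its acquisition (`R/phantom.R`); slice preparation (`R/slice_prep.R`);
intensity-stage registration (`R/local_phase.R`, `R/register.R`);
contours-stage registration (`R/register_contours.R`); the shape model and
stage C (`R/ssm.R`); surface reconstruction (`R/tps.R`, `R/surface_recon.R`);
tetrahedralization and quality (`R/volmesh.R`); activation simulation
(`R/eikonal.R`); orchestration and I/O (`R/pipeline.R`, `R/io.R`) with a thin
command-line front end in `inst/cli/`.
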