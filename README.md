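# cinemesh

Simulation-ready 3D biventricular heart meshes from misaligned 2D cine-MR
slices.

Standard cardiac cine MRI acquires a stack of short-axis (SAX) slices plus a
few long-axis (LAX) views, one breath-hold each. Because the heart does not
return to exactly the same position between breath-holds, the slices are
mutually misaligned in 3D, and a surface naively fitted through their contours
is distorted. `cinemesh` implements an automated pipeline that turns such a
set of arbitrarily oriented slices — images with full 3D pose metadata plus
per-slice label masks or contours — into a smooth, watertight biventricular
surface and a quality-audited tetrahedral mesh suitable for electrophysiology
simulation, together with a forward anisotropic Eikonal activation-time
solver.

## The method

Let slice *i* carry a rigid pose correction Θ*ᵢ* (3 translations + 3 Euler
angles about the slice axes). The misalignment correction minimises the
global motion discrepancy

    GM(Θ₁, …, Θₙ) = Σ_{i,j intersecting} E(Sᵢ^{Θᵢ}, Sⱼ^{Θⱼ})

by sequentially re-posing one slice at a time (bounded pattern search with a
simplex polish), LAX slices first, in three stages:

1. **Intensity stage** (in-plane Θ): `E = 1 − NCC` of local-phase profiles
   sampled along each slice pair's intersection line. Local phase comes from
   banks of quadrature log-Gabor filters and is invariant to the intensity
   inconsistencies between slices.
2. **Contours stage** (in-plane Θ): `E` is the mean Euclidean distance
   between matched contour crossings of the intersection line (per anatomical
   label: LV endocardium, LV epicardium, RV endocardium, septum).
3. **Shape-model stage** (full 6-DOF Θ): a PCA shape model (mean surface +
   orthonormal modes) is fitted to the sparse 3D contours — alternating
   nearest-point correspondence, a closed-form rigid update, and a per-mode
   ridge-regularised coefficient solve — and each slice is then rigidly
   re-aligned to the fitted surface, freeing the through-plane motion the
   first two stages cannot observe. The fitted model is then discarded.

The three surfaces (LV endocardium, RV endocardium, epicardium) are
reconstructed from the aligned contours by lofting the per-slice loops,
iterative thin-plate-spline deformation toward the contour points,
attractor-based separation of intersecting endo/epicardial surfaces, and a
basal join into one watertight biventricular surface. A body-centred-cubic
lattice tetrahedralizer fills it at a 1.5 mm element size, audited by the
Knupp index (min-over-corner scaled Jacobian: 1 = regular tetrahedron,
0 = degenerate). The Eikonal solver then computes activation times per vertex
under orthotropic conduction speeds with a fast endocardial layer, for
comparison against reference epicardial maps by Pearson correlation.

Everything is validated end-to-end on a built-in analytic biventricular
phantom (nested truncated-ellipsoid LV, crescent RV with a genuine septum)
with known ground truth: exact implicit surfaces, simulated cine slices with
label masks, analytic contours, seeded misalignment injection, and a
synthetic PCA shape model built from a seeded phantom population.

## Worked example

```r
library(cinemesh)

spec <- phantom_spec()                      # the default biventricular phantom
run  <- run_pipeline(pipeline_config(seed = 42, misalign_tz = c(-3, 3)), spec)

subset(run$ladder, label == "POOLED")
#>        stage  label      mean        sd     n
#>  uncorrected POOLED 1.7284008 1.2101838 15078
#>    intensity POOLED 1.2364360 1.1833961 15078
#>     contours POOLED 0.3537779 0.3252197 15078
#>          ssm POOLED 0.1512536 0.1978576 15078

run$quality
#> <mesh_quality: 62209 nodes, 302841 elements, Knupp 0.8175 +/- 0.1506, 2.32% below 0.50>
```

The ladder lists the mean distance from every contour point to the final
reconstructed surface with the slices at each stage's poses: the injected
misalignment (in-plane amplitude calibrated to a pre-correction pooled level
of about 1.8 mm against the ground-truth surfaces, plus +-3 mm through-plane
offsets) shrinks monotonically — the intensity stage gives a coarse initial
alignment, the contours stage removes most of the in-plane error, and the
shape-model stage resolves the through-plane component. `run$quality` is the
Knupp-index (scaled Jacobian) audit of the tetrahedral mesh at the default
1.5 mm element size.

Individual stages are plain functions over plain objects —
`classify_slices()`, `masks_to_contours()`, `correct_intensity()`,
`correct_contours()`, `fit_ssm()`, `align_slices_to_model()`,
`reconstruct_surfaces()`, `tetrahedralize()`, `quality_summary()`,
`solve_eikonal()` — see the vignette for the full tour. A thin command-line
front end is installed at `inst/cli/cinemesh` (subcommands `phantom`, `ssm`,
`run`, `quality`, `simulate`).

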