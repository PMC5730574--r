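---
title: "Nuclear morphometry and actin-cap cell mechanics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and actin-cap cell mechanics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nucmorph quantifies three-dimensional nuclear morphology from confocal-style
z-stacks and solves a simplified mechanical model of an adherent cell under
substrate stretch, with and without a perinuclear actin cap. This vignette
explains the methods, the tunable parameters, the synthetic-data design, and
the numerical choices, including the places where the design was genuinely
open and what we decided.

## The measurement problem

Adherent fibroblast-like cells respond to uniaxial cyclic stretch of their
substrate by re-orienting away from the stretch axis and by remodelling their
nuclei: the nucleus flattens at conserved volume when a perinuclear actin cap
(apical actomyosin bundles anchored at large peripheral focal adhesions)
forms, and becomes laterally lobed and rough when the cap cannot form, as in
lamin-A/C-deficient cells. Quantifying these phenotypes needs a small set of
3D shape metrics, and interpreting them needs a mechanical model of how the
cap redistributes stretch-induced forces.

## Morphometry from z-stacks

A stack is a `(z, y, x)` intensity array with physical voxel sizes; z
increases apically. The pipeline is:

1. **Segmentation** (`segment_nucleus()`): Otsu threshold on the pooled
   histogram, morphological closing (1 voxel; skipped for already-binary
   input so segmentation is idempotent), largest 26-connected component,
   hole filling. The original method asserts that its reconstructed outer
   surface is threshold-independent; since the mechanism is unpublished, we
   operationalize the claim as a *threshold-sensitivity score* — the maximal
   relative volume change under a ±10% threshold perturbation — reported
   with every segmentation rather than assumed.
2. **Volume**: foreground voxel count × voxel volume.
3. **Thickness**: per-(x, y)-column z-extent, maximized over columns. For a
   tilted nucleus this follows the object rather than its bounding box.
4. **Footprint area and shape factor**: the mask is projected onto the XY
   plane (a column with any foreground voxel is footprint). Area is the
   pixel-count area. The shape factor is the circularity 4πA/P² of the
   sub-pixel footprint outline (Gaussian-smoothed field, 0.5 contour), which
   the isoperimetric inequality bounds by 1, so "rounder = higher" holds by
   construction.
5. **Surface extraction** (`extract_surface()`): marching tetrahedra on the
   Kuhn 6-tet subdivision of the blurred mask (σ = 1 voxel), 0.5 isosurface,
   sub-voxel edge interpolation. Marching tetrahedra has no ambiguous sign
   cases, so the mesh is guaranteed closed and manifold; we verify Euler
   characteristic 2 and use the divergence-theorem volume as an independent
   cross-check of the voxel-count volume (they agree within 2% on phantoms).

## Texture: amplitude profiles, bumpiness, roughness

Lateral texture is measured on cross-sections at three altitudes — 25, 50
and 75% of the nuclear height measured *down from the apex* (top, middle,
bottom). Each section contour is traced by casting rays from the section's
own area centroid through the Gaussian-smoothed mask field (sub-pixel 0.5
crossing); a unique crossing per ray is required, and a non-star-shaped
section aborts with the offending angle. The *amplitude profile* is the
centre-to-boundary distance as a function of angle, sampled clockwise from
+x and normalized by the equivalent circular radius r_eq = sqrt(A/π). The
normalization gives a scale-free invariant, mean(value²) = 1, which follows
from A = ½∮r²dθ and is asserted in the tests.

Profiles are smoothed with a Savitzky–Golay filter of polynomial degree 6.
The window length is not specified by the source method; we default to 31
samples of 360 (about 31°), which suppresses pixelation noise while leaving
lobes up to k ≈ 12 intact. Peaks are circular local maxima with topographic
prominence ≥ 0.01 (relative-radius units); the prominence floor is ours, it
exists to ignore machine-precision ripples, and it is exposed as an
argument. A circle has 0 peaks, a smooth ellipse exactly 2 (its major-axis
tips), and a k-lobed contour k. *Lateral bumpiness* is the mean peak count
over the three altitudes.

*Surface roughness* takes the vertical cross-section through the footprint
centroid (the XZ plane by default), extracts the sub-voxel apical height
profile h(x), removes a smooth baseline (Savitzky–Golay, degree 6, window =
¼ of the profile length), and reports the RMS residual divided by the
lateral extent of the scanned surface. Whether the original "height
variation" was RMS, SD or range is unstated; RMS is the default and the
others are selectable (`stat=`), as is averaging over several azimuthal
sections (`n_sections`). The ratio is dimensionless and scale-invariant,
which the tests verify by rescaling phantoms.

## Cell orientation

Orientation is the unsigned acute angle between the longest chord through
the cell mask and the stretch axis, folded into [0°, 90°]; uniformly random
orientations then average 45°, which is the natural baseline (a signed
convention would average 90°). The chord is the exact diameter of the
convex hull of foreground pixel centres (verified against brute force over
all boundary pixels). We do not constrain the chord to pass through the
centroid — the source defines only "the longest chord through the cell".

One accuracy caveat is intrinsic: near the maximum, chord length varies only
quadratically with angle, so all chords within a few degrees of the true
axis differ by less than one pixel. A single mask's measured angle therefore
carries ~2–3° of quantization noise at 0.5 µm pixels regardless of
estimator; population means are unaffected (the noise is symmetric), and
near-circular masks whose near-maximal chords disagree by more than 1° are
flagged `degenerate`.

## Synthetic phantoms: what they emulate, what they do not

No imaging data accompany the study, so every stage is exercised on
parametric phantoms with analytic ground truth:

- **Nuclei**: ellipsoids (a, b, c) with lateral cosine lobes
  r(θ) = r₀(θ)(1 + A·cos kθ) applied uniformly in z (smooth = wild-type-like,
  lobed = lamin-deficient-like), a vertical flattening factor (stretch
  response), and an apical cosine ripple (surface wrinkling). Intensity is
  binary (0.9 object / 0.1 background) plus Gaussian noise; optional
  Gaussian blur stands in for mild optics. Default test conditions use
  0.05–0.25 µm voxels, lobe amplitudes 0.08–0.15 and noise SD up to 0.1 —
  amplitudes chosen so lobes are comparable to the reported phenotype
  (clearly visible but < 20% of radius); they are calibration knobs, not
  claims about real nuclei.
- **Calibration bead**: a 2 µm sphere at 0.05 µm voxels mirrors the
  fluorescent-microsphere validation of the volume pipeline.
- **Cell masks**: rasterized ellipses (default aspect ratio 3, major axis
  40 µm, 0.5 µm pixels) with controllable orientation law (uniform, fixed,
  wrapped normal).

Phantoms do not emulate the microscope PSF, photobleaching, intensity
gradients, touching objects or time-lapse registration; passing tests
demonstrate correctness of the *metrics*, not robustness to every imaging
artefact.

## The finite-element cell model

The model has three phases: a flattened-dome cytoplasm (radius 25 µm,
peripheral height 2 µm, apex 6 µm, parabolic profile), an ellipsoidal
nucleus (8 × 6 × 3 µm semi-axes, resting on the basal plane, apex touching
the dome — a spread fibroblast's nucleus spans essentially the full cell
height), and, when the cap is present, seven fiber beams. 42 circular
conventional focal adhesions (CFAs, 2.3 µm² each; deterministic sunflower
packing) and 14 elliptical actin-cap-associated focal adhesions (ACAFAs,
4 × 1 µm, fanned across two opposed ±15° peripheral sectors on the stretch
axis) sit on the basal plane; each fiber connects an opposed ACAFA pair,
ramping up from the adhesion and hugging the nucleus apical surface.

Discretization: a mirror-symmetric, boundary-fitted structured tetrahedral
mesh (triangulated disk extruded through the dome in layers; prisms split by
the sorted-global-index rule, which keeps faces conforming), with elements
labelled nucleus or cytoplasm by centroid. Elements are 4-node constant
strain tets by default or 10-node quadratic tets (the element family of the
original model) as a fidelity option; both pass patch tests and have exactly
six rigid-body modes. Fibers are 3-node shear-deformable (Timoshenko)
beams assembled from exact interdependent-interpolation halves — free of
shear locking and nodally exact for end loads (the cantilever closed form
PL³/3EI + PL/κGA is reproduced to machine precision). Circular cross-section
radius 0.2 µm, κ = 0.9.

Default materials (package defaults in the physiological literature range,
*not* measured values, all overridable): cytoplasm E = 1 kPa, nucleus
E = 5 kPa (ν = 0.37), fiber E = 1.45 MPa (ν = 0.3). Units are µm and Pa, so
forces are pN.

Loading follows the stretch experiment: at focal-adhesion nodes the
longitudinal displacement u_x = 0.08·x is prescribed, transverse in-plane
motion is free, and the whole basal plane is restrained out-of-plane. One
central basal node is pinned in y to remove the in-plane rigid mode, and
fiber-end rotations are clamped (adhesion plaques anchor the fiber ends).
The static system is solved by direct sparse factorization with a fixed node
ordering, so runs are deterministic; relative residuals are ~10⁻¹⁴ and
reaction forces balance to ~10⁻¹⁵ relative.

### Interfaces: tied by default, contact as an option

The original model couples its phases by frictionless contact. A faithful
contact solver is out of proportion for this package's scope, so the default
is the conventional surrogate: one conforming continuum with the fiber beam
nodes tied to the solid displacement field by interpolation (MPC), and fiber
ends tied to their ACAFA nodes. Because this choice is consequential (see
below), both one-sided alternatives are implemented and selectable:
`fiber_coupling = "normal"` lets the fiber slide along its own axis and
press — never pull — the material beneath it, and
`nucleus_coupling = "normal"` duplicates the interface nodes and transmits
only compressive normal tractions, each resolved by active-set iteration
(release pairs whose constraint would act in tension, re-engage pairs that
would interpenetrate, repeat to a fixed point).

### What the cap does in this model — and what it does not

With the default tied interfaces, adding the seven fibers concentrates
reaction force at the ACAFAs: the conventional-FA share of total reaction
force drops by roughly 40–55% (robust across all coupling variants except
the fully released one), consistent with the reported cap-induced
redistribution (> 20%).

The nuclear-stress half of the comparison behaves differently. An embedded
fiber bonded to the material is strained with it — at 8% stretch each fiber
carries on the order of E_f·A·0.08 ≈ 15 nN — and a taut arch pressing on the
nucleus it spans raises the mean nuclear von Mises stress (by ~175% at the
defaults) instead of lowering it. The unilateral-contact variants do not
rescue the reported reduction either: at these soft literature-range
parameters the fiber path has geometric slack, most contact releases, and
both cap effects vanish. Reproducing the reported > 30% nuclear-stress
reduction evidently requires the original study's material/geometry table,
which is not publicly available; at this package's defaults the cap
comparison reports a stress *increase*, and we document that honestly rather
than tune parameters toward the published number. The accompanying
fiber-stiffness sweep (`fiber_stiffness_sweep()`) makes the sensitivity
explicit: in the tied model, nuclear stress rises monotonically with fiber
modulus while the force-redistribution effect stays strong throughout.

### Numerical sizes and convergence

Desk-scale defaults are mesh_h = 2 µm with 4 vertical layers (~2,700 nodes,
~12,000 linear tets; a cap comparison solves in seconds). A quadratic solve
at the same spacing is ~100× slower in this pure-R assembly and is reserved
for the `tet_order = "quadratic"` option. Mean nuclear von Mises changes by
~12% (no cap) to ~20% (with cap) between mesh_h = 2 and mesh_h = 1: the
nucleus–basal contact point is a weak corner singularity and tied fibers
apply line-like loads, both of which converge slowly in 3D elasticity. The
class fractions and the cap deltas, which are the quantities compared,
change by only a few points between these meshes.

## Sub-pixel boundaries and aliasing

All sub-pixel boundary work (section contours, apical height profiles,
footprint outlines) interpolates a Gaussian-smoothed copy of the binary
mask. The smoothing scale is σ = 1.5 voxels for the texture metrics: at
σ = 1 the pixelation aliasing of mildly eccentric sections can reach the
0.01 peak-prominence floor and create spurious peaks, while σ = 1.5 damps
it well below the floor and still recovers cosine lobes up to k = 10 under
10% intensity noise (surface extraction uses σ = 1, where only metric
accuracy matters). Two sampling caveats follow from the same analysis. First, the residual
radial ripple of a rasterized circular boundary is ~2% of radius at 30
pixels and plateaus near 0.8% beyond ~60 pixels — at the prominence floor —
so peak counts of *near-circular* sections can include an occasional
marginal aliasing peak; genuinely lobed sections (amplitude ≥ 5%) are far
above the floor and count exactly. Second, a boundary radius that is an
exact voxel multiple places boundary voxel centres exactly on the surface
along the axes, a measure-zero worst case for aliasing that real data
cannot produce; tests use off-grid radii.

## Degenerate inputs and tie-breaks

- Constant or empty stacks, empty masks and empty slices raise typed errors
  (`nucmorph_no_object`, `nucmorph_empty_mask`).
- Multiple similar-size components warn and keep the largest.
- Chord ties are broken by first occurrence in hull order; near-circular
  masks set a `degenerate` flag rather than erroring.
- The isosurface level is nudged by 10⁻⁷ off 0.5 to avoid exact-symmetry
  vertex hits of the blurred binary field.
- FA centres are snapped to distinct basal mesh nodes so every adhesion has
  at least one constrained node at any mesh density; patch reactions are
  summed over all nodes inside the footprint.

## Known limitations

Static, linear-elastic, small-strain mechanics only — no viscoelasticity,
no cyclic loading, no remodelling; the contact options are bilateral-mesh
penalty approximations with linearized kinematics, not large-sliding
contact; morphometry assumes a single star-shaped-per-section nucleus; and
the synthetic phantoms span the reported phenotypes but not the full
variability of real nuclei.
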