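---
title: "Region-growing condyle segmentation: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-growing condyle segmentation: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condyseg)
```

## The segmentation model

The condyle is brighter than its soft-tissue surroundings in CBCT, but
by a margin that varies across the scan: CBCT grey values are not
calibrated Hounsfield units, the cone-beam geometry adds position-
dependent noise and inhomogeneity, and the partial-volume effect blurs
the cortical boundary. A single global threshold therefore cannot trace
the condylar outline reliably. The protocol implemented here replaces it
with a *locally varying* threshold:

- On every annotated slice $s_i$ (recommended: every fifth slice), the
  observer supplies a seed pixel inside the condyle and a threshold
  $t_i$ that makes the 2D 8-connected region grown from the seed fit the
  outline on that slice.
- For all other slices the threshold $t(s)$ is linearly interpolated in
  slice index between the neighbouring annotations and held constant
  beyond the first and last one. Linear interpolation with constant
  extrapolation is the lowest-order rule that reproduces the annotated
  values exactly and cannot overshoot between annotations.
- The segmentation is the connected component, seeded at the central
  seed, of $\{v : I(v) \ge t(\mathrm{slice}(v))\}$ inside the VOI.

Thresholds are *inclusive lower bounds* with no upper bound: condylar
bone is the bright extreme of its neighbourhood, and the interactive
protocol exposes a single adjustable threshold per slice. The default 3D
connectivity is 6 (face neighbours); diagonal (26) connectivity is
available but leaks more easily through the one-voxel gap between
condyle and fossa, which is exactly the failure mode the protocol tries
to avoid.

**The central seed.** The 3D growth starts from the seed of the
annotation whose slice is closest to the median annotated slice (ties
resolved toward the lower slice). Any annotation can be designated
instead via `central_index`. The choice only matters if the admissible
set is disconnected across the VOI; the median-slice rule picks a seed
deep inside the condylar head, far from both VOI borders.

**Indexing convention.** All indices in the R API and in the JSON config
dialect are 1-based and inclusive (a VOI is `[lo, hi]` per axis), the
native R convention; mm coordinates assign voxel $(i,j,k)$ the box
$\mathrm{origin} + ((i,j,k)-1)\cdot\mathrm{spacing}$ to
$\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$.

## Post-processing

Corrections are pure slice-level edits (OR or replace of one in-plane
label), applicable along any of the three axes, mirroring the
interactive correction loop. They run before opening, so the opening
also cleans correction artifacts; `keep_seed_component()` runs last.

"Opening with a structural element of size three" is interpreted as a
$3^3$ cube by default — the shape is not otherwise constrained — with
`cross` and `ball` variants provided. Erosion treats the outside of the
grid as background, which is the conservative choice for structures near
the VOI edge (a condyle touching the VOI face loses its one-voxel rind
rather than gaining one). On phantom condyles the size-3 opening removes
well under 2% of the voxels (asserted in the test suite), consistent
with the protocol's premise that only small condyle–fossa connections
are at stake; the element size is exposed for pathologies where that
premise fails.

## Surface extraction

Installed R packages provide no marching-cubes implementation, so the
iso-surface of the 0/1 grid is extracted exactly rather than
approximately: every voxel face separating foreground from background
becomes two outward-oriented triangles on the voxel-corner lattice. For
a binary grid this *is* the 0.5-level boundary of the voxel-as-cube
model, and it makes the enclosed mesh volume equal the voxel-count
volume to machine precision — a stronger guarantee than an interpolated
tessellation provides, at the cost of a staircase appearance.

The staircase is relaxed by Taubin smoothing ($\lambda = 0.5$,
$\mu = -0.53$, default 10 iterations), chosen over plain Laplacian
smoothing because its alternating inward/outward steps avoid systematic
shrinkage: on phantom condyles 10 iterations change the enclosed volume
by less than 2%. Because any smoothing still has *some* systematic
effect on shape, all meshes that enter a comparison should be extracted
with identical settings — the package's own benchmark does so, and the
distance-map functions take the meshes as given.

## Validation statistics

- **Dice** is computed on voxel masks, not meshes; it is the agreement
  measure for the segmentation itself, before any rendering choices.
- **Distance maps** sample each surface (all vertices plus
  area-proportional deterministic face samples, default 4 per mm²) and
  measure exact point-to-triangle distances to the other mesh,
  accelerated by a uniform spatial grid. The symmetric mode pools both
  directed distance sets, making the summary invariant to argument
  order; directed mode is kept for diagnosing one-sided errors.
  Percentiles use the linear-interpolation convention (R type 7), which
  the reported 90th percentiles depend on.
- **ICC** is the single-measure two-way absolute-agreement coefficient
  computed from the standard mean squares of the subject-by-rater table
  without replication. For absolute agreement the mixed- and
  random-effects formulations coincide, so one formula serves.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a ground-truth condyle (ellipsoidal head,
default semi-axes 5 × 4.5 × 4.5 mm, on a cylindrical neck of radius
2.2 mm reaching 10 mm below the head centre) at 0.4 mm isotropic voxels
in a 64³ grid, spanning roughly 40 axial slices — the scale at which the
protocol expects 8–9 annotated slices at the default spacing of five.
The image model layers the CBCT artifacts that motivate the design:

- a fossa-like bright shell 1.2 mm above the head, connected to it by
  `n_bridges` (default 2) single-voxel bright bridges — the spurious
  connections that opening must sever. Bridges are painted at full bone
  intensity after the blur: a one-voxel structure would otherwise be
  washed out by the partial-volume model, and the bridges exist to
  create the worst case, not an average one;
- linear axial intensity drift (default 0.5 units/slice, ~20 units
  across the condyle) — the minimal inhomogeneity under which local
  thresholds demonstrably beat the best single global threshold (a test
  asserts this);
- Gaussian partial-volume blur (σ = 0.3 mm) and additive Gaussian noise
  (σ = 10 on a 140-unit bone–soft contrast, roughly the contrast-to-
  noise regime of clinical CBCT);
- a per-phantom log-normal size factor (σ = 0.08, i.e. ±8% linear, ±24%
  volumetric) emulating anatomical variation between subjects. Without
  it every default phantom would be congruent and the between-subject
  ICC undefined; with it the simulated volume table has a realistic
  spread relative to observer error.

The simulated observer annotates every fifth truth-containing slice,
seeds at the in-plane truth centroid (±1 voxel uniform jitter,
constrained to the truth), and picks the threshold from a grid
(90–180, step 5) maximizing the in-plane Dice of the 2D grown region
against the truth slice — an operationalization of tuning the outline
"by eye" — with ties to the lowest threshold (observers trace the outer
cortical boundary) and truncated Gaussian noise (σ = 5) added. The
magnitudes of seed jitter and threshold noise are assumptions, not
measurements: no quantitative observer-noise data exist for this
protocol, so they are set to produce visible but sub-voxel disagreement
and are exposed in `observer_params()` for sensitivity analysis.

What the phantom does **not** model: real condylar shape variation
(flattening, erosions, osteophytes), motion artifacts, streak/beam-
hardening artifacts, the true spatial correlation of CBCT noise, or a
physics-based projection/reconstruction chain. Passing the phantom
benchmark therefore demonstrates the *internal* consistency and
observer-robustness of the pipeline under the modelled artifacts — it
does not certify accuracy on patient anatomy, for which a cadaver or
laser-scan ground truth would be needed.

## Benchmark design and problem sizes

`bench_experiment()` runs 10 phantoms × 2 independent simulated
observers (the package's analog of a two-observer, ten-patient
validation): 64³ volumes, full protocol per observer (growth, opening
with the cube-3 element, seed-component keeping), meshes at 10 Taubin
iterations, distance maps at 2 samples/mm². These sizes keep a full run
around half a minute on one core while leaving every stage — including
bridge capture and removal — genuinely exercised. Per-phantom and
per-observer seeds are derived arithmetically from one master seed, so
the whole experiment is reproducible bit for bit, and observer streams
are separate from phantom streams so observers can be varied on a fixed
phantom.

## Numerical and degenerate-case choices

- `grow_2d`/`grow_3d` reject a seed below its own threshold — the
  observer chose an impossible pair — rather than returning an empty
  region; an empty growth result is therefore impossible.
- Dice of two empty masks and the ICC of a constant table are errors,
  not 0/1: both are undefined limits and silently returning a value
  would hide upstream failures.
- Raw export is uint8 0/1, C-order, little-endian with a mandatory JSON
  sidecar; the format is self-describing so round-trips are exact and
  testable.
- DICOM reading supports explicit-VR little-endian uncompressed series
  (the common export case) and fails loudly otherwise; slice spacing
  inconsistencies beyond 1% are format errors. Grey values are used as
  stored (after slope/intercept); no HU calibration is attempted because
  CBCT HU values are unreliable by construction.
- The NIfTI path preserves data and spacing; mm origins are carried by
  the raw sidecar dialect.

## Known limitations

- The cuberille surface has axis-aligned normal quantization before
  smoothing; sub-voxel surface localization (as a grey-level marching
  cubes would give) is out of scope since all masks are binary.
- One annotation axis per 3D run; combining thresholds chosen on
  different axes into a single run is not supported (corrections on any
  axis are).
- The simulated observer requires ground truth, so it cannot be used on
  patient data; it exists to validate the pipeline, not to replace the
  human.
- `icc_absolute_agreement()` can return $-\infty$ for adversarial 2×2
  tables whose absolute-agreement denominator vanishes; this is the
  formula's true limit and is not masked.
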