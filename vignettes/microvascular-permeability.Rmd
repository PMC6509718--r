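---
title: "Computing Darcy permeability tensors of microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing Darcy permeability tensors of microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microperm)
```

## The model

Capillary beds are too dense to prescribe boundary conditions vessel by
vessel, but at tissue scale their flow behaves like flow through a porous
medium: Darcy's law relates the volume flux to the pressure gradient
through a 3×3 permeability (conductivity) tensor **K**. `microperm`
computes **K** for a vascular graph — segments with radius `r` and
geodesic length `l` between 3D node positions inside a rectangular domain —
by homogenization:

1. Each segment carries Poiseuille flow, `q = π r⁴ Δp / (8 μ l)`, with the
   apparent blood viscosity `μ` from an empirical in-vitro law of diameter
   and discharge hematocrit.
2. Conservation of flow at every interior node yields a sparse symmetric
   linear system in the nodal pressures.
3. A uniform pressure gradient (1 Pa/μm by default; the tensor is
   gradient-invariant by linearity) is applied along one axis via Dirichlet
   pressures on the two opposing faces, while nodes on the four lateral
   faces are merged with their periodic partners on the opposite face.
4. Entry `k_ij` is the net flux through the face normal to axis `j` divided
   by that face's area and the applied gradient. Repeating for the three
   gradient directions fills the tensor, reported in mm³·s/kg
   (1 μm²/(Pa·s) = 10⁻³ mm³·s/kg).

Anatomical networks are not periodic. Before solving, the domain is
reflected across its upper x, then y, then z faces, producing a volume of
doubled extents containing eight mirrored copies. Opposite outer faces are
then mirror-identical, so every lateral node has an exact periodic partner.
Reflection is an involution, so mirroring twice must not change the tensor;
`permeability_tensor(..., mirror_times = 2)` exposes this internal
validation, and the test suite holds it to 10⁻⁸ relative on every fixture.

## Preparing anatomical data

Real reconstructions are disconnected (and the disconnections may be
pathology, so no gap-closing is attempted). `preprocess_network()` runs, in
order:

- **Component labelling and density filtering.** Connected subnetworks are
  labelled (0 = largest) and only those holding at least 15% (inclusive) of
  the total vascular volume are retained. Vascular density is implemented
  as the cylinder-volume fraction Σπr²l — the closest graph analogue of
  image vascular density, since graph input has no voxels.
- **Border elongation.** Degree-1 nodes within `epsilon` (default 5 μm,
  roughly a few z-voxels of typical confocal stacks) of a domain face are
  translated onto the face, their segment lengthened accordingly. This
  protects branches that stop just short of the section border from being
  pruned. Corner ties break toward the lower axis index for determinism.
- **Blind-end pruning.** Segments ending at an untagged degree-1 node are
  removed iteratively (cascades allowed) until every end node lies on a
  face. Blind ends are sprouts or imaging artifacts and carry no flow
  between faces. The operation is idempotent.
- **REV gating.** Homogenization needs a representative elementary volume:
  subnetworks whose post-pruning bounding box measures under 170 μm along
  x or y (inclusive threshold) are excluded. z is not gated because the
  slab thickness (~100 μm) is below the cutoff by construction.
  `rev_scan()` recomputes tensors over a range of unit sizes to expose this
  dependence; unit decomposition clips vessels at unit borders exactly as
  cutting an image volume would.

Per-subnetwork tensors are fused by a surface-weighted average
(`fuse_tensors()`): each subnetwork's weight along direction `j` is its
mirrored bounding-box face area divided by the union area covered by all
subnetworks, with pairwise projected-bbox overlaps subtracted (higher-order
overlaps are not corrected). Because pruning removes real vascular volume,
each tensor is additionally rescaled by `V_init/V_pruned ≥ 1`;
`apply_scale = FALSE` reproduces the unscaled variant for comparison.
The fused tensor is finally sorted (`sort_tensor()`) by a simultaneous
row/column permutation so `k11 ≥ k22 ≥ k33`, making images with arbitrary
mounting orientation comparable.

## Blood rheology

Two hematocrit modes are available (`rheology_params()`):

- `constant_hct` (default): every segment carries the inlet discharge
  hematocrit (default 0.4) and viscosity follows the in-vitro
  apparent-viscosity law, which reproduces the Fåhræus–Lindqvist minimum
  near 7 μm diameter. Plasma viscosity defaults to 1.2 mPa·s and rescales
  the tensor inversely; setting `rheology_params(1, 0)` gives constant
  1 mPa·s viscosity for closed-form work.
- `phase_separation`: red cells split unevenly at diverging bifurcations
  (plasma skimming). The empirical logit law (diameter-ratio and
  hematocrit terms, zero-flux cutoff `X₀ = 0.964(1−H)/D_f`) assigns
  erythrocyte flux fractions at two-daughter branchings; at three or more
  daughters, where the law is undefined, red cells follow the flow and a
  warning is logged. `update_hematocrit()` propagates discharge hematocrit
  in topological order of the flow orientation (flow descends pressure, so
  the orientation is acyclic; segments carrying only roundoff-level flow,
  |Q| ≤ 10⁻¹² max|Q|, are treated as stagnant to keep it so), mixing
  conservatively at converging nodes. The solve and a damped update
  (damping 0.5) alternate until max |ΔH| < 10⁻⁴ or 100 iterations;
  non-convergence returns the last iterate flagged in the tensor metadata.
  These scheme constants are package choices — declared, not derived.

## Perfusion and remodeling

`mbf_from_k()` converts a diagonal tensor element to myocardial blood flow
(mL/min per 100 g) given an arteriole–venule pressure drop (default
19.5 mm Hg), a microvascular path length (default 512 μm, the porcine
mean; 349 and 675 bracket ±1 SD) and myocardial density (default
1.05 g/cm³, a standard value — configurable because it is not known
exactly for any given sample). `dp_from_mbf()` is the exact algebraic
inverse, used to estimate the pressure drop from measured flow; it scales
with the square of the path length.

`apply_scenario()` implements six remodeling families: uniform or random
subset dilation/constriction of diameters, diameter-dependent vasodilation
(linear response, maximal at 0.4 μm diameter, zero at 20 μm), and pruning
of the smallest-radius segments (count-based, floor rounding, ties by
segment id, followed by a re-run of blind-end pruning). Subset selection
uses an explicit recorded seed so scenarios are bit-reproducible. With
constant viscosity, uniform dilation by `f` changes every diagonal by
exactly `(1+f)⁴ − 1`; with the viscosity law active, constriction pushes
capillaries toward steeply rising viscosity below the Fåhræus–Lindqvist
minimum, so a 30% constriction loses more than the constant-viscosity
75.99%.

## What the synthetic generators emulate

`make_single_tube()`, `make_parallel_tubes()` and `make_cubic_lattice()`
are oracle fixtures with closed-form tensors. The default lattice is
*staggered*: lines run half a spacing away from the lateral faces and meet
the domain faces through perpendicular stubs, so each line carries exactly
one s×s unit cell and the closed form πr⁴/(8μs²) holds exactly after
mirroring. The plain node-on-face variant (`staggered = FALSE`) is kept
for grid-counting contracts, but its face-plane lines are shared between
periodic images, inflating the diagonal by ((2n−1)/(2n−2))² — a
finite-size artifact, not a solver error.

`make_random_capillary()` emulates the thin-slab anatomical data the
pipeline is designed for: a staggered lattice (default 320×320×80 μm,
spacing 40 μm, of the order of intercapillary distance) with jittered
interior nodes, log-normal radii (median 4 μm, σ_log 0.3,
capillary-dominated), blind ends carved by construction, border ends
retracted a few micrometers (exercising elongation), and a detached
secondary component imitating pathology-related disconnection.
`perturb_mi_like()` adds the late-infarct phenotype: enlarged vessels and
capillary loss. What these fixtures do **not** reproduce is the
tortuosity, anisotropy and heterogeneity of real myocardium — so passing
tests demonstrate correctness of the algorithms and conservation laws, not
agreement with any particular biological measurement; synthetic-bed
tensors are roughly an order of magnitude above measured basal myocardium
values because the emulated bed is denser and straighter than real tissue.

## Numerical choices and problem sizes

- Sparse symmetric direct factorization (Matrix package) with residual
  check against `solver_config(tol = 1e-10)`; components unreachable from
  the pressure boundaries are excluded (zero flow) rather than making the
  system singular; a direction with no face-to-face connectivity returns a
  legitimate all-zero tensor row.
- Conductances guard radii below 0.1 μm to avoid underflow (warned).
- Periodic partners are matched by exact in-face coordinates, which
  mirroring guarantees bit-identically; node merging uses a 1 μm face
  tolerance (`face_tol`, about one z-voxel of the source imaging).
- Degenerate bounding boxes (straight or planar components with zero
  extent on an axis) fall back to the parent-box extent along the
  collapsed axes, since a zero-thickness domain has no face to normalize
  by.
- The test suite runs on fixtures of a few hundred segments (mirrored:
  a few thousand), chosen so the full suite completes in well under a
  minute while still exercising every code path; the acceptance script
  uses a ~400-segment bed.

## Limitations

- Steady Poiseuille flow only: no pulsatility, vessel compliance, or
  junction losses.
- The phase-separation law is defined for bifurcations; higher-order
  branchings fall back to flow-proportional red-cell splitting.
- Fusion corrects pairwise surface overlaps only.
- The pressure-drop inversion assumes the arteriole–venule path length is
  condition-independent.
- Tensor values scale inversely with the assumed plasma viscosity and
  directly with the fourth power of radii, so segmentation bias in radii
  dominates the error budget of any real application.
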