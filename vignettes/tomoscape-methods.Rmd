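---
title: "tomoscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tomoscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoscape)
```

# Scope

`tomoscape` implements the quantitative scene-analysis steps used to
characterize membrane-associated macromolecular particles in cellular
cryo-electron tomograms: bilayer thickness from intensity profiles,
membrane meshing with leaflet-resolved thickness maps, per-vertex
curvature tensors, particle-pair spatial/orientational statistics, and
desk-scale constrained cross-correlation (CCC) template scoring.  A
seeded synthetic-scene generator supplies every input the pipeline
needs, so the full analysis runs and is tested without raw tomographic
data.  Upstream steps that require dedicated external tools --
tilt-series reconstruction, CTF correction, neural membrane
segmentation, large-scale template matching, subtomogram averaging --
are out of scope; segmentations and pose tables are inputs here.

# Coordinate and unit conventions

All lengths are nanometres internally; Angstrom values are converted at
I/O boundaries (an 8.704 Å/px header reads as 0.8704 nm voxels).  Voxel
indices are 0-based and the world position of the centre of voxel
`(i, j, k)` is `origin + (c(i, j, k) + 0.5) * voxelSize`; the half-voxel
offset makes mask, mesh and pose frames agree exactly.  Rotations are
stored as proper 3x3 matrices mapping the particle frame to the world
frame; on disk, pose tables carry intrinsic ZXZ Euler triples in
degrees (`R = Rz(phi) Rx(theta) Rz(psi)`), the dominant
subtomogram-averaging convention.

# Bilayer thickness from intensity profiles

In cryo-ET density the two lipid leaflets appear as dark bands, so a
profile extracted along the membrane normal shows two minima flanking a
central maximum.  `detectBilayerFeatures()` selects the two most
prominent minima (prominence computed on the inverted signal; ties are
broken toward the profile centre), centres the profile on the maximum
between them, and reports two readouts:

* **minima-based thickness** -- the distance between the two leaflet
  minima;
* **inflection-based thickness** -- the distance between the two
  inflection points, each located as the maximum absolute intensity
  gradient (central differences) between a minimum and its adjacent
  maximum.

"Adjacent maximum" is ambiguous: each minimum has an inner flanking
maximum (the bilayer centre) and an outer one.  Both readings are
implemented behind `inflectionSide`; the default is `"outer"`, which
spans the full bilayer and includes the leaflet widths (for an ideal
two-Gaussian profile with trough width `sigma` it converges to
`t + 2*sigma`).  All extremum and gradient positions are refined to
sub-sample precision with 3-point parabolic interpolation; at 0.87 nm
sampling the voxel quantization would otherwise dominate the
measurement.

A numerical point worth knowing: profiles are sampled from the volume
by trilinear interpolation, which is piecewise linear along the
extraction axis.  Sampling *finer* than the voxel size therefore pins
minima to grid knots and destroys sub-voxel localization, while
voxel-spaced samples follow the smooth underlying density and refine
well.  The default profile spacing is accordingly the voxel size.

# Membrane meshes, leaflets and thickness maps

`maskToMesh()` triangulates the segmentation at iso level 0.5 using
marching tetrahedra (each grid cube is split into six tetrahedra
sharing a main diagonal).  This decomposition is topologically
unambiguous, needs no large case table, and places every surface vertex
on a unique grid edge, which makes vertex de-duplication exact.  Binary
masks are box-smoothed once (3x3x3) before extraction: raw binary data
would put every surface crossing at an edge midpoint, faceting the
surface and inflating its area by ~20%, while the smoothed 0.5-crossing
of a flat interface stays on the true boundary plane by symmetry.  With
the smoothing pass, the measured area of a digitized ball of radius 20
voxels is within 0.2% of the analytic sphere area.  Face winding is
oriented along the density gradient (away from the segmented region).

Vertex normals start as angle-weighted averages of incident face
normals; `refineNormals()` optionally applies rounds of area-weighted
neighbour averaging, which helps when the surface itself is noisy.

`separateLeaflets()` assigns each vertex to one of the two membrane
surfaces.  A global principal-component split fails on curved
membranes, so the implementation is local: vertices within a
neighbourhood radius (callers use about three bilayer thicknesses; the
radius must exceed the sheet separation so both sheets enter each
neighbourhood) define, by PCA, a local sheet plane and its minor axis;
the vertex's signed offset from the local centroid along the minor axis
decides its side.  Minor-axis orientation is made globally consistent
by breadth-first flood fill over mesh connectivity -- breadth-first
deliberately, because depth-first paths can carry an orientation flip
picked up where the minor axis turns sideways (e.g. at a thickness
step) deep into the sheet.  Local planes are estimated on an evenly
spaced reference subset (~2500 vertices) and inherited by nearest
reference; the local plane varies slowly compared to the vertex
spacing, so this changes nothing but the cost.

`computeThicknessMap()` enforces the one-to-one matching rule:
candidate pairs (each leaflet-A point with its nearest leaflet-B point)
are sorted by ascending distance and accepted greedily, skipping pairs
that would reuse a matched point and rejecting pairs beyond
`maxPairDistance`.  Greedy ascending-distance acceptance is
deterministic, order-independent after sorting, and optimal for
well-separated sheets.  A consequence to keep in mind when summarizing:
points whose nearest partner was already consumed stay unmatched, so
locally thin regions (shorter pairs, accepted first) are matched
slightly more completely than thick ones.

# Curvature tensors

`curvatureField()` implements the per-face curvature-tensor estimator
for irregular triangle meshes.  For each face, the symmetric 2x2 second
fundamental form `II` is fitted by least squares over the three edges
from `II e = dn` (edge vectors and vertex-normal differences projected
into the face tangent frame; 3 unknowns, 6 equations).  Face tensors
are transported into each incident vertex's tangent frame by the
minimal rotation between face and vertex normals and averaged with
mixed-Voronoi corner weights (plain Voronoi areas for acute triangles,
area/2 at an obtuse corner and area/4 elsewhere, keeping all weights
positive).  Eigen-decomposition gives principal curvatures `k1 >= k2`
and directions, with `H = (k1 + k2)/2` and `K = k1 k2` exactly by
construction.

The sign convention follows the supplied normals: normals spreading
apart along an edge (a surface bulging toward its normal) give positive
curvature, so with cytosol-facing normals an indented membrane has
negative mean curvature.  Flipping all normals negates `H` and leaves
`K` unchanged.  On a 2562-vertex sphere of radius 10 nm with analytic
normals the median `H` and `K` are exact to well under 1%, and the
Voronoi-weighted total Gaussian curvature reproduces the
Gauss--Bonnet value `4*pi` to 0.1%.

# Particle pose context

`pairNearest()` realizes the encapsulation rule: a ribosome is paired
with its nearest vault (per tomogram) if and only if their centres are
at most 10 nm apart (inclusive); equidistant vaults resolve to the
lower index.  The relative rotation is fixed as
`R_rel = t(R_vault) %*% R_ribosome`, and the plotted quantity is a
ribosome reference axis expressed in the vault frame
(`relativeAxis()`); both the reference axis and the comparison target
axis are explicit parameters, since the source convention is not
standardized.  The construction is invariant under a common global
rotation of both pose sets.

Spherical histograms bin directions into the spherical Voronoi cells of
the face centroids of a subdivided icosahedron (80 bins at one
subdivision) -- a near-equal-area partition with an unambiguous
assignment rule (nearest centroid).  `classifyRTC()` labels a pair
"RTC-like" when its relative axis lies within `thetaRtc` of the target
axis; the default half-angle is 30 degrees with the boundary inclusive,
exposed as a parameter because published analyses of this kind rarely
print their bin edges.  The contingency summaries
(`orientationContingency()`, `encapsulationSummary()`,
`classFractionSummary()`) consume either computed labels or printed
count tables directly.

# Template scoring

`cccScore()` is a deliberately desk-scale reimplementation of
single-particle constrained cross-correlation scoring, not a
whole-tomogram search engine.  The score of a subtomogram `s` against a
template `t` under a mask `M` (default: centred sphere) at rotation `R`
is the zero-lag normalized cross-correlation of the mask-standardized
volumes,

```
CCC(R) = (1/|M|) * sum_M  s~ * (T_R t)~ ,
```

where `~` denotes subtraction of the mask mean and division by the mask
standard deviation, and `T_R` is trilinear rotation about the volume
centre.  Subtomograms are assumed particle-centred, so only the zero
translational lag is scored.  When a missing wedge is declared, both
spectra are multiplied by the same binary wedge mask (tilt axis y)
before standardization, so template and data see identical frequency
support.  Scores are exactly affine-invariant in either input and
bounded in [-1, 1].

The rotation grid places axis directions on a spherical Fibonacci
lattice at the requested angular step and samples the in-plane angle at
the same step, restricted to the `[0, 360/n)` fundamental domain of a
Cn symmetry.  Grid sizes are reported in the returned object; exact
grid constructions differ between packages and none is canonical.
`peakZscore()` / `thresholdPeaks()` reproduce peak cleaning by z-score
(default threshold 18), and `assignClass()` labels a subtomogram by the
higher of two template scores, with an exact tie going to the first
template under a logged warning.

# The synthetic-scene generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under.

* **Bilayer scenes** (`makeBilayerScene()`): density
  `I = -A g(d1; sigma) - A g(d2; sigma) + noise` with Gaussian troughs
  of width `sigma = 1` nm and leaflet separation `t = 6` nm at 0.87 nm
  voxels (4x-binned tomogram sampling); an optional circular patch of
  reduced thickness (`patchThinning`) and a Gaussian indentation ring
  of the mid-surface emulate the membrane geometry under a bound
  particle.  Leaflets are dark (minima), matching cryo-ET contrast; an
  inversion flag exists because normalized maps do not fix the
  convention.  Ground truth (local thickness, mid-surface mean
  curvature) comes from the closed-form geometry.
* **Oracle meshes** (`makeParametricMesh()`): plane, icosphere,
  cylinder and saddle with analytic curvature; jittered vertices are
  re-projected onto the analytic surface so the analytic values stay
  exact at the final positions.
* **Pose populations** (`makePosePopulation()`): vault centres packed
  with 40 nm minimum separation in a 500 nm box; exactly
  `floor(fraction * n)` vaults per class receive a ribosome placed
  uniformly within 8 nm of the vault centre -- strictly inside the
  10 nm pairing rule, so recovery truth is unambiguous -- while free
  ribosomes stay at least two cutoffs away.  Concentrated relative
  orientations draw the reference axis from a von Mises--Fisher
  distribution (inverse-CDF sampling of the cosine) with uniform spin;
  `kappa = 100` gives a ~6 degree angular spread, of the order of a
  tightly ordered particle population.
* **Subtomograms** (`makeSubtomograms()`): rotated copies of one of two
  asymmetric blob-composite templates (both are deliberately free of
  any self-rotation, so the best-scoring orientation is well defined),
  optionally wedge-filtered, plus white Gaussian noise.  The wedge is
  applied to the rotated template before the noise is added, keeping
  the noise white and the SNR interpretable.

All generators draw from per-operation streams derived from the master
seed by fixed labels (`deriveSeed()`), so adding one generator call
does not shift the random numbers of another, and every scene is
bit-reproducible.

What the generator does **not** emulate: CTF modulation, tilt-series
acquisition and reconstruction artifacts beyond the binary wedge,
correlated (non-white) noise, membrane undulations, crowding, or
segmentation errors.  Passing tests therefore demonstrate correctness
of the measurement logic under controlled geometry, not robustness to
every property of real tomograms.

# Numerical choices and degenerate inputs

* Sub-sample localization everywhere by 3-point parabolic refinement.
* Low-pass filtering uses a raised-cosine edge (default width 20% of
  the cutoff frequency, exposed) since no edge shape is canonical; the
  DC term is preserved exactly.
* The Wiener-like deconvolution uses a pure exponential amplitude-decay
  contrast model; no defocus parameters are invented.
* Mann-Whitney: `U = min(Ux, Uy)` with midranks; exact null
  distribution up to n = 25 per group without ties (covering the n = 20
  case exactly), otherwise a normal approximation with tie and
  continuity correction.  Fisher's two-sided p sums hypergeometric
  masses not exceeding the observed table's mass.
* Degenerate inputs fail loudly: constant volumes (z-score), profiles
  without two minima, masks without an iso crossing, single-sheet
  meshes, zero-spread score populations, zero-margin tables (warned,
  p = 1).
* Problem sizes used by the test suite and the acceptance script --
  2562-vertex spheres, 48^3-voxel scenes, 40 subtomograms on a
  15-degree grid -- were chosen as the smallest sizes at which the
  estimators reach their asymptotic behaviour.

# Known limitations

* Leaflet separation assumes a locally two-sheet geometry; closed
  vesicles smaller than the PCA radius and branching membranes are not
  separable and are rejected rather than guessed.
* The CCC scorer searches rotations only; a translational search
  beyond particle-centred extraction is out of scope.
* The inflection-point thickness readout depends on the chosen adjacent
  maximum (inner vs outer); both are reported options, and comparisons
  should fix one basis per analysis.
* Greedy one-to-one matching slightly under-samples thick regions (see
  above); group comparisons based on medians are insensitive to this.

# Session

```{r}
sessionInfo()
```
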