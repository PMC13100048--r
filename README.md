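# tomoscape

Quantitative in-situ analysis of membranes and particle context in
cryo-electron tomograms.

Cellular cryo-electron tomography (cryo-ET) resolves macromolecular
particles — such as the barrel-shaped vault ribonucleoprotein — in
their native membrane and ribosome context. Turning those scenes into
numbers requires a set of recurring measurements that `tomoscape`
implements as a tested, reusable R toolkit for structural cell
biologists:

* **Bilayer thickness from intensity profiles.** Membrane leaflets
  appear as two density minima along the membrane normal. For a
  profile `I(x)` the package reports both standard readouts: the
  distance between the two leaflet minima, and the distance between
  the two inflection points — the positions of maximal |dI/dx| between
  each minimum and its adjacent maximum — with sub-voxel parabolic
  refinement.
* **Leaflet-resolved thickness maps.** Segmentation masks are
  triangulated (marching tetrahedra at iso 0.5), the two leaflet
  surfaces are separated by local PCA with flood-fill label
  consistency, and per-point thickness is the Euclidean distance
  between one-to-one matched nearest-neighbour points on the opposing
  surfaces.
* **Membrane curvature.** Per-face curvature tensors are fitted by
  least squares from vertex-normal differences across each triangle,
  accumulated at vertices with mixed-Voronoi area weights, and
  eigen-decomposed into principal curvatures `k1 >= k2`, with
  `H = (k1 + k2)/2` and `K = k1 * k2`; indented membranes have `H < 0`
  for cytosol-facing normals.
* **Particle pose context.** Nearest-neighbour pairing under a centre
  distance rule (10 nm for vault-encapsulated ribosomes), relative
  orientations `R_rel = R_vault^-1 R_ribosome`, spherical histograms
  on subdivided-icosahedron bins, RTC-like orientation classification,
  and the exact contingency statistics built from such counts
  (two-sided Fisher exact test, exact two-tailed Mann-Whitney U).
* **Template scoring.** Desk-scale constrained cross-correlation
  (masked, standardized, zero-lag, optionally missing-wedge
  compensated) over a near-uniform rotation grid with Cn symmetry
  reduction, z-score peak thresholding, and two-template (e.g.
  80S vs 60S ribosome) class assignment.
* **Synthetic scenes.** A seeded generator produces bilayer volumes
  with known thickness/curvature ground truth, analytic-curvature
  oracle meshes, vault/ribosome pose populations with controllable
  encapsulation and orientation concentration, and toy subtomograms —
  so the whole pipeline runs without any raw tomographic data.

Volumes are read and written as MRC (voxel size in the header, Å ↔ nm
converted), particle poses as tab-separated motive-list tables
(positions in voxels, intrinsic ZXZ Euler angles in degrees), meshes as
binary PLY with per-vertex attributes.

## Worked example

Measure a synthetic membrane patch of locally reduced thickness — the
geometry observed under membrane-bound vaults — and run the printed
count statistics:

```r
library(tomoscape)

sc   <- makeBilayerScene(bilayerSpec(gridShape = c(48, 48, 40),
                                     thickness = 6, troughWidth = 1,
                                     patchRadius = 12, patchThinning = 1,
                                     seed = 1))
mesh <- refineNormals(maskToMesh(sc$mask, smoothPasses = 0), 1)
mesh
#> TriMesh: 18430 vertices, 36104 faces, with normals

lf   <- separateLeaflets(mesh, neighborhoodRadius = 18)
tmap <- computeThicknessMap(lf, maxPairDistance = 15)
ctr  <- c(24, 24) * 0.87
r    <- sqrt((tmap$ax - ctr[1])^2 + (tmap$ay - ctr[2])^2)
sprintf("median thickness: inside patch %.2f nm, outside %.2f nm",
        median(tmap$thickness[r < 10]), median(tmap$thickness[r > 14]))
#> "median thickness: inside patch 6.98 nm, outside 8.11 nm"

fisherExactTwoSided(contingency2x2(80, 905, 4, 10))
#> Fisher's exact test (two.sided, exact): statistic = 0.220994,
#>   p = 0.02425, n = 985/14

mannWhitneyTwoTailed(c(21:39, 15.5), 1:20)   # a U = 5 configuration
#> Mann-Whitney U test (two.sided, exact): statistic = 5,
#>   p = 2.757e-10, n = 20/20
```

The thickness map recovers the 1 nm thinning of the patch (the mask
envelope adds one trough width per leaflet to the absolute values,
which is why the medians sit above the leaflet separation; the
*difference* is the measurand). The Fisher table above — 80 of 985
cytosolic vaults versus 4 of 14 membrane-bound vaults with an
encapsulated ribosome — gives p = 0.0242; the `U = 5` Mann–Whitney
configuration with 20 measurements per group gives a two-tailed
p < 1e-4.

A curvature check on an analytic oracle:

```r
sph <- makeParametricMesh(meshSpec("sphere", radius = 10,
                                   targetVertexCount = 2562))
cf  <- curvatureField(sph$mesh)
cf
#> CurvatureField over 2562 vertices
#>   median H = 0.1 1/nm, median K = 0.01 1/nm^2
```

## Package layout

* `R/` — S4 classes (`DensityVolume`, `SegmentationMask`, `TriMesh`,
  `PoseSet`, `CurvatureField`) and the analysis modules.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (closed forms, brute-force enumeration,
  Monte-Carlo sampling).
* `vignettes/tomoscape-methods.Rmd` — the models, conventions, default
  parameters and numerical choices, and what the synthetic scenes do
  and do not emulate.
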