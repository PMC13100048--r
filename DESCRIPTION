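Package: tomoscape
Title: Quantitative In Situ Analysis of Membranes and Particle Context in
    Cryo-Electron Tomograms
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of cryo-electron tomography
    scenes: bilayer thickness measurement from intensity profiles along the
    membrane normal, triangular meshing of membrane segmentations with
    leaflet separation and one-to-one nearest-neighbour thickness maps,
    per-vertex principal/mean/Gaussian curvature via face curvature tensors
    with Voronoi-area accumulation, ribosome-vault spatial and orientational
    context statistics (nearest-neighbour pairing, spherical histograms,
    exact contingency tests), and desk-scale constrained cross-correlation
    template scoring with missing-wedge support. A seeded synthetic-scene
    generator provides bilayer volumes, parametric meshes with analytic
    curvature, pose populations and toy subtomograms, so the full pipeline
    runs without raw tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Software, Visualization, StructuralPrediction
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'curvature.R'
    'membrane-mesh.R'
    'mrc-io.R'
    'pose-context.R'
    'pose-io.R'
    'profile-thickness.R'
    'stats-tests.R'
    'synth-bilayer.R'
    'synth-mesh.R'
    'synth-poses.R'
    'synth-subtomo.R'
    'template-score.R'
    'utils.R'
    'volume-prep.R'
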