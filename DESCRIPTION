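Package: hypoparc
Title: Diffusion-Based Parcellation of the Hypothalamus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated parcellation of the hypothalamus from single-shell
    diffusion-weighted MRI. Estimates constant-solid-angle q-ball orientation
    distribution functions (ODFs) in a real even-order spherical-harmonic
    basis, clusters voxels with an equal-weighted k-means on standardized
    spatial coordinates and ODF coefficients, selects the number of clusters
    by the Davies-Bouldin index, labels the four resulting subunits
    anatomically, fuses per-subject parcellations into a majority-voting
    probabilistic atlas, and relates subunit-wise mean diffusivity to
    body-mass index with reliability statistics (Dice, ICC). Includes a
    multi-tensor DWI phantom generator with Rician noise for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    pracma,
    withr,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'cluster.R'
    'cohort.R'
    'dwi.R'
    'features.R'
    'gradients.R'
    'hypoparc-package.R'
    'io.R'
    'mask.R'
    'phantom.R'
    'pipeline.R'
    'sh.R'
    'stats.R'
    'utils.R'
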