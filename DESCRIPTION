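Package: fcparc
Title: Connectivity-Based Parcellation and Group Inference for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for data-driven parcellation of an anatomical mask into
    subregions with distinct resting-state functional connectivity fingerprints.
    Covers motion scrubbing (framewise displacement and DVARS), 24-parameter
    motion and tissue principal-component nuisance regression, band-pass
    filtering, voxelwise connectivity fingerprints with Fisher r-to-z
    transforms, average-linkage hierarchical clustering with silhouette-based
    selection of the number of clusters, Dice-similarity matching of group
    clusters to single-subject solutions, probabilistic atlases with
    winner-take-all labeling, and permutation-based general linear models on
    seed-to-voxel maps with age and voxel-dependent grey-matter interactions.
    A synthetic-phantom module generates multi-subject cohorts with known
    parcel structure, motion artifacts and planted group effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
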