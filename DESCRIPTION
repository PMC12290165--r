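Package: nihssRSC
Title: Ordinal Symptom Similarity Networks, Repeated Spectral Clustering
    and Voxel-Wise Lesion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised stratification of stroke cohorts from ordinal
    symptom scales (NIHSS-style item scores). Patient-to-patient
    dissimilarity is computed with the rank-sign General Distance Measure
    (GDM), whose complement yields a weighted similarity network. The
    network is partitioned with Repeated Spectral Clustering (RSC):
    N runs of normalized symmetric Laplacian spectral clustering are
    accumulated into a co-clustering consensus matrix, which is itself
    spectrally clustered; the number of clusters is chosen from the
    consensus eigengap profile. Cluster-specific binary lesion masks are
    summarized as voxel-wise density maps, and one-vs-rest proportion
    tests with Westfall-Young step-down maxT permutation correction
    identify voxels lesioned at significantly different frequencies,
    with Bonferroni control across cluster families. A synthetic-cohort
    generator with planted symptom prototypes and lesion loci supports
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
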