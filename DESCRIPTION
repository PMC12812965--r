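Package: gliofuse
Title: Multimodal MRI-Genomic Fusion for Brain Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a multimodal pipeline for brain tumor classification
    that fuses volumetric MRI with gene-expression data. The imaging branch is
    a 3D densely connected convolutional encoder; the genomic branch is a
    two-layer graph attention network over a gene-interaction graph; the two
    are combined by spatial cross-modal graph attention followed by adaptive
    modality-attention fusion, and classified through a dense head with a
    sparse entmax-alpha output. Includes NIfTI volume preprocessing (brain
    masking, z-score normalization, trilinear resampling), expression quality
    control and co-expression graph construction, a seeded generator of paired
    synthetic cohorts with planted class signal, CPU-scale training of the
    fusion and classification layers over fixed random-feature encoders, an
    ablation harness, and a classification-metrics toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
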