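Package: mudkit
Title: Multimodal Omics Containers with HDF5 Serialisation and Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-memory container for multimodal omics experiments (RNA,
    chromatin accessibility, surface proteins) with union-of-cells axis
    semantics, cross-modality subsetting and metadata push/pull; a
    self-describing HDF5 serialisation dialect (.h5mu) with standalone
    per-modality readability and disk-backed (lazy) count matrices;
    per-modality preprocessing (library-size log-normalisation, scaling,
    highly variable feature selection, TF-IDF/LSI for accessibility,
    background-based denoising of epitope counts); multimodal integration
    via weighted nearest neighbours for an arbitrary number of modalities
    and a deterministic joint factorisation with per-modality variance
    decomposition; seeded synthetic multiome and CITE-seq generators; and
    a command-line surface for inspection, validation, subsetting and
    simulation of .h5mu files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    rhdf5,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
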