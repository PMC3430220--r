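Package: sofmrbf
Title: Descriptor Clustering and RBF-Network Correction of DFT Bond
    Dissociation Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical correction of DFT-calculated Y-NO homolysis bond
    dissociation energies. Molecular descriptors are clustered with a
    Kohonen self-organizing feature map, one representative per cluster is
    kept by correlation with experiment, and an exact-design Gaussian
    radial-basis-function network regresses experimental values on the
    selected descriptors. Ships fixtures transcribing the benchmark
    per-molecule deviation and cluster-label tables, and a synthetic-data
    generator reproducing the benchmark's statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
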