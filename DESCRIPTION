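Package: metabotensor
Title: Multiway Analysis of Simulated Dynamic Metabolomics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cohorts of time-resolved metabolomics profiles from
    kinetic ODE systems with individual (random) and induced (group-wise)
    variation, arranges them as subjects x metabolites x time tensors, and
    disentangles the sources of variation with CANDECOMP/PARAFAC (CP) and
    Paralind (restricted CP with linearly dependent subject-mode factors)
    tensor factorizations.  Includes a full model-selection toolkit:
    explained fit, the core consistency diagnostic, Tucker's congruence
    coefficient, subject-mode cosine similarity, and missing-data
    cross-validation via the tensor completion score with paired testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
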