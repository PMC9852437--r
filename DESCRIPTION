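Package: snapfam
Title: Compound Family Annotation of Molecular Networking Subnetworks from MS1 Masses
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates connected components (subnetworks) of MS2 molecular
    networks with natural-product compound families using only MS1 precursor
    masses. Subnetwork masses are binned into compound groups, matched against
    a structure reference database (Natural Products Atlas, COCONUT, or a
    synthetic fixture database) through a panel of positive-mode adducts, and
    the pooled candidate structures are clustered into compound families by
    chemical-fingerprint similarity (Morgan, MACCS, or atom-pair fingerprints
    with Dice or Tanimoto scoring). Families are ranked by how many subnetwork
    masses their members explain. Also provides the two supporting analyses:
    molecular-formula tuple diagnosticity statistics over database compound
    families, and a fingerprint/metric/cutoff selection benchmark against a
    reference MS2 molecular network, plus a seeded synthetic-fixture generator
    for ground-truthed end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR
Suggests: testthat (>= 3.0.0)
SystemRequirements: OpenBabel 3 ('obabel' on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
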