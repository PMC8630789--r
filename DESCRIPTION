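Package: bitterspace
Title: Scaffold Decomposition and Chemical-Space Profiling of Bitter Taste
    Receptor Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemoinformatic characterization of food bitter compounds against
    the 25 human bitter taste receptors (TAS2Rs). Implements Bemis-Murcko
    framework extraction and all-orders scaffold-network enumeration,
    per-receptor unique-scaffold statistics and scaffold-per-compound ratios,
    receptor and compound promiscuity indices, receptor-superclass-promiscuity
    alluvial flow aggregation, public 166-key MACCS structural fingerprints,
    and an exact-gradient t-SNE embedding of the fingerprint chemical space.
    Includes a synthetic compound-library and activation-matrix generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
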