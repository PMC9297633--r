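Package: myconet
Title: Plant-Fungus Bipartite Interaction Networks from Root Mycobiome
    Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds species-level plant-fungus bipartite interaction
    networks from sample-level fungal OTU read-count tables and analyses
    their structure and specialization. Interactions are called from read
    counts under a joint relative-abundance and contamination-floor rule;
    networks of three types (binary, abundance, incidence) are scored for
    connectance, checkerboard score, binary and weighted nestedness
    (NODF2), and Barber bipartite modularity, and plant-level and
    network-level specialization is quantified with normalized degree,
    Bluthgen's d' and H2'. Significance is assessed against quasiswap,
    Patefield (marginal) and shuffle-sample permutation null models, and
    networks are compared through a bipartite motif census with node
    positions. Compositional analyses (Bray-Curtis, PERMANOVA, PCoA,
    neighbor-joining dendrograms) and a synthetic read-table generator
    with planted nested or modular structure complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
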