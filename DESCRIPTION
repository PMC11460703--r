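Package: meiorec
Title: Tetrad-Based Meiotic Recombination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls and classifies crossover (CO) and noncrossover (NCO)
    recombination events from four-spore tetrad segregation data and computes
    the crossover-control statistics used in comparative yeast recombination
    studies: gamma-model crossover interference on inter-CO genetic distances,
    coefficient-of-coincidence curves, chromatid interference, CO homeostasis,
    dispersion of per-chromosome CO counts, non-exchange (E0) chromosome
    inventories with Poisson expectations, permutation-based CO hotspot and
    coldspot detection with synteny-based conservation, and gene-level
    molecular evolution statistics (Nei-Gojobori pairwise dN/dS, nucleotide
    diversity, Watterson's theta, median-rank enrichment). Includes a
    gamma-renewal meiosis simulator that generates tetrad datasets with ground
    truth so that every stage of the pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
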