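Package: eaemap
Title: EAE Clinical-Course Phenotyping, Multiparent QTL Mapping, and
    Network-Based Candidate Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives quantitative trait variables (cumulative disease
    scores, incidence, disease-course classes) from daily experimental
    autoimmune encephalomyelitis (EAE) clinical scores, including humane
    endpoint and mortality carry-forward rules; maps those traits to
    genomic loci by regression on eight-founder haplotype probabilities
    of multiparent recombinant inbred panels such as the Collaborative
    Cross, with rank-based inverse normal transformation, batch
    residualization, optional kinship correction, permutation-based
    genome-wide thresholds, founder allele effects, and Bayesian credible
    intervals; and prioritizes positional candidate genes with an
    ensemble of linear support vector machines over tissue-specific
    functional gene networks, scored by an averaged false positive rate.
    Includes seed-deterministic simulators for score trajectories,
    founder-mosaic genomes with planted QTL, gene networks with planted
    trait modules, and variant tables, so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
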