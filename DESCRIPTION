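Package: mir140sim
Title: Stochastic and Deterministic Kinetic Models of miR-140 Regulatory
    Motifs in Osteoarthritis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic models of gene-regulatory network motifs
    through which the chondrocyte microRNA miR-140 acts in osteoarthritis:
    five single-pathway models (TGF-beta/SMAD3 positive feedback,
    SOX9/RUNX2 incoherent feedforward, IL-1/ADAMTS5 coherent feedforward,
    IL-1/NF-kB/MMP13 incoherent feedforward, TNF-alpha/IGFBP5/IGF-1
    incoherent feedforward) and an integrated cartilage-degradation model,
    simulated exactly by the Gillespie direct method or deterministically
    by LSODA. Includes generic feedback/feedforward motif models,
    intervention presets (knockdown, overexpression, anti-miR titration),
    in-silico experiment runners with ensemble summaries, SBML
    import/export, a hypergeometric miRNA target-set enrichment pipeline,
    and a synthetic-data generator with planted enrichment structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Rcpp,
    xml2,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
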