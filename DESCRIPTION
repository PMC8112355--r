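Package: sterolpath
Title: Sterol Biosynthesis Pathway Inference from Semi-Quantitative GC-MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to go from semi-quantitative GC-MS sterol profiles to
    ab-initio biosynthesis pathway models and phylogenetic support mapping.
    Steroid molecules are modelled as relational fact sets on the standard
    numbered carbon skeleton; molecular transformations are signed fact-set
    diffs that can be derived from substrate/product pairs, applied to new
    substrates, and matched at relaxed positional level to gap-fill pathways
    for specialized metabolites. Peak tables are identified against a
    standards registry by linear retention index and spectral similarity,
    quantified with internal-standard relative response factors, and reduced
    to percent-composition profiles with a not-detectable threshold. Pathway
    support states derived from the profiles are mapped on a phylogeny by
    stochastic character mapping under a symmetric-rates continuous-time
    Markov model, with ancestral node state frequencies summarised from
    sampled character histories. Synthetic-data generators emulate each input
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
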