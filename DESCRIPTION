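Package: founderage
Title: Dating Founder Mutations from Linkage Disequilibrium Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the age, in generations, of a founder disease mutation
    from case-control marker data flanking the disease locus. Implements the
    Risch-style single-marker estimator based on the decay of linkage
    disequilibrium, a Labuda-style growth correction calibrated by branching
    genealogy simulation, a modified Goldgar multi-marker likelihood that
    scans outward from the disease locus allowing recombination and marker
    mutation and weights over each carrier's possible haplotypes, and the
    demographic arithmetic (growth rates from census pairs, generation-year
    conversion) used to interpret the estimates. Includes a forward-in-time
    simulator of founder haplotypes under exponential population growth with
    known truth, an enumeration-based phasing EM, and a configuration-driven
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
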