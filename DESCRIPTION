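Package: jakscreen
Title: Consensus Filtering and Clinical Statistics for Targeted JAK2
    Hotspot Sequencing
Version: 0.1.0
Authors@R: person("jakscreen", "maintainers", email = "jakscreen@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for hotspot mutation screening from targeted
    amplicon deep sequencing in childhood B-cell precursor acute
    lymphoblastic leukemia. Reads multi-caller VCF dialects, normalizes and
    merges variant calls, applies a ten-rule consensus filter cascade
    (region, multi-caller, coverage, alt reads, cohort VAF presence,
    run-balance chi-square, COSMIC membership, amino-acid change, known-SNP
    and germline heuristics), quantifies subclonal detection limits from
    depth, and implements the downstream clinical statistics: CRLF2
    expression classification, comparative-Ct relative expression, Fisher
    exact MRD-relapse association, Aalen-Johansen cumulative incidence under
    competing risks with Gray's K-sample test, and ex vivo drug-response
    normalization. A synthetic-cohort generator emulates the study design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
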