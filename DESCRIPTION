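Package: hotspotr
Title: Detection and Passenger Annotation of Somatic Mutation Hotspots
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects recurrently mutated protein positions (hotspots) in
    cancer cohorts from MAF-style mutation tables using a per-gene
    beta-binomial model with stepwise fixed effects, assigns upper-tail
    p-values with Benjamini-Hochberg false discovery rate correction and
    recurrence filters, and annotates candidate hotspots for likely
    passenger mechanisms: APOBEC3A DNA-hairpin stem strength scoring of
    the genomic context, and a simplified gene-level dN/dS selection
    estimate. Includes a synthetic cohort and hairpin fixture generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
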