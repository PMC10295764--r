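Package: pooldeg
Title: Evaluate Pooled-Sample RNA-Seq Designs for Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ask whether sequencing a single pooled RNA sample
    recovers the same differentially expressed genes as sequencing
    biological replicates individually. Provides a negative-binomial
    count simulator with known truth labels and in-silico equal-mass
    pooling of replicates, counts-per-million normalisation and per-gene
    group summaries, a family of fold-change and standard-deviation DEG
    criteria alongside a Welch-t / Benjamini-Hochberg significance route,
    gene-set concordance statistics (percent overlap on the smallest-set
    denominator, fold enrichment with hypergeometric significance,
    identification and accuracy percentages, multiway Venn partitions,
    identifier harmonisation), and an orchestrator that runs complete
    simulated replicate-versus-pooled studies with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
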