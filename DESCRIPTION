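Package: kdscreen
Title: Knockdown Connectivity Screening and Multifaceted Assessment of
    Therapeutic Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and prioritizes candidate therapeutic targets from
    RNA-interference knockdown transcriptomes. Builds tumor-versus-normal
    query signatures with an empirical-Bayes moderated t-statistic, scores
    them against a knockdown reference database with the weighted
    Kolmogorov-Smirnov connectivity statistic, and filters the resulting
    candidates through a multifaceted assessment: up-regulation in tumors,
    expression-linked poor survival (Kaplan-Meier, log-rank, Cox), promoter
    hypomethylation on 450k-style beta values, cancer-gene membership and
    druggability, with hypergeometric enrichment of filter intersections.
    Includes a synthetic-data generator that plants known differential
    expression, signature-reversing knockdowns, hazard effects and
    hypomethylated blocks so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
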