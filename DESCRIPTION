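Package: adpgx
Title: Candidate-Gene Pharmacogenetic Analysis of Antidepressant Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for candidate-gene pharmacogenetic studies of
    antidepressant response in two-site cohorts. Derives the four standard
    treatment-response outcomes (remission, response, percentage change in the
    21-item Hamilton Rating Scale for Depression, and the depressed-mood stem
    item) from longitudinal clinical assessments, multiply imputes missing
    follow-ups with Rubin pooling, applies sample- and marker-level genotype
    quality control (plate call rates, inbreeding, identity-by-state kinship,
    multidimensional-scaling outliers, exact Hardy-Weinberg tests), fits
    additive single-marker regressions adjusted for sex and age, runs
    LD-pruned gene-based set tests with permutation empirical p-values, and
    combines sites by Fisher's combined-probability (inverse-Gamma) meta-analysis
    alongside a pooled mega-analysis with LD-adjusted significance thresholds.
    Ships a synthetic two-site cohort generator (Gaussian-copula linkage
    disequilibrium blocks, longitudinal severity trajectories, realistic
    missing-data pattern mixtures) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
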