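Package: testcross
Title: Line x Tester Combining Ability, Heterotic Grouping and SNP
    Diversity for Testcross Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-environment line x tester analysis for maize testcross
    trials evaluated under Striga-infested and non-infested conditions:
    sequential ANOVA with an incomplete-block (alpha-lattice) term, general
    and specific combining ability (GCA/SCA) effects with standard errors,
    heterotic-group-specific combining ability (HSGCA), expected-mean-square
    variance components with narrow-sense heritability and repeatability,
    standard heterosis against a tester-cross check, infestation yield loss,
    and two heterotic-group classifiers (SCA plus yield; HSGCA) with
    cross-condition consensus. A companion marker module performs SNP panel
    QC (missingness, major allele frequency, heterozygosity), diversity
    summaries (gene diversity, PIC, observed heterozygosity), Jaccard and
    identity-by-state distances, Ward clustering with silhouette-based
    cluster-number selection, and genotype PCA. Synthetic-data generators
    for both the field trials and the inbred SNP panel make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
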