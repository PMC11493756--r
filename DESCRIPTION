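Package: poolscape
Title: Pool-Seq Population Genomics of Structured Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled whole-genome population genomics of structured
    metapopulations along environmental gradients: reading and filtering
    popoolation2-style sync allele counts, genome scans for selection
    (Omega-corrected XtX, C2 contrasts for binary covariables, generalized
    least-squares environmental association, quasibinomial allele-frequency
    GLMs with genomic-control recalibration and Storey q-values),
    pool-corrected diversity statistics (pi, Watterson theta, Tajima's D),
    population structure (pairwise FST, UPGMA with bootstrap, Mantel tests of
    isolation by distance and environment, Forstner-Moonen matrix distance),
    and two-population demographic inference from the folded joint site
    frequency spectrum by Monte-Carlo structured-coalescent composite
    likelihood under seven competing split/bottleneck/migration models.
    Includes a forward Wright-Fisher metapopulation simulator with pooled
    read sampling so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    ape,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
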