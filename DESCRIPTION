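Package: popgenpipe
Title: Population-Genetic Inference from SNP Panels: f-Statistics, IBD
    Sharing, Founder Events and Hierarchical AMOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for the population-genetic analysis of
    diploid biallelic SNP panels from structured populations, motivated by
    the demographic history of South American indigenous groups. Provides
    genotype panel input/output (VCF, PLINK-style and EIGENSTRAT-style
    text), quality-control and LD pruning, a forward Wright-Fisher
    simulator with planted ground truth, f2/f3/f4 statistics with weighted
    block-jackknife errors and admixture-graph fitting, supervised ancestry
    estimation, ordination and genetics-versus-geography regressions,
    PLINK-style relatedness and runs-of-homozygosity calling with F_ROH
    summaries, identity-by-descent segment detection on phased haplotypes
    with ancestry masking and time stratification, founder-event dating
    from the decay of allele-sharing correlation, effective-population-size
    history from the IBD length spectrum, and hierarchical analysis of
    molecular variance with permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    minpack.lm,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
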