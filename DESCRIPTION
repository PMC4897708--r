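Package: largv
Title: LD-Adjusted Regional Genetic Variance from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the phenotypic variance explained by a genomic region
    from genome-wide association summary statistics while accounting for
    linkage disequilibrium (LD). Each SNP's squared standardized effect is
    deflated by the sum of its squared correlations with neighbouring SNPs,
    summed over the region, and centred so the estimate has zero expectation
    under the null. Includes a greedy algorithm that partitions chromosome
    arms into SNP blocks minimizing cross-boundary LD, the individual-level
    adjusted-R-squared comparator the summary-statistic estimator is
    asymptotically equivalent to, an enrichment test for excess regional
    variance around a locus, a polygenic-trait simulator with controllable
    LD, PLINK/VCF readers, quality-control filters, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
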