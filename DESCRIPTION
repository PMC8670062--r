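Package: popprs
Title: Population-Level Polygenic Risk Scores from Risk-Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population-specific polygenic risk scores (psPRS) as
    unweighted sums of risk-allele frequencies over a SNP set, regresses
    trait prevalence (or mean height) on the score under linear,
    second-order polynomial and exponential links, and prunes SNPs by
    greedy maximization of the coefficient of determination. Includes the
    follow-up statistics used to characterise pruned SNP sets (Fisher
    exact enrichment of genome-wide-significant SNPs, allele-frequency
    mean comparisons, discovery-ancestry percentages, physical SNP
    spacing summaries) and a seeded Balding-Nichols-style synthetic-data
    generator so the whole pipeline is testable without external
    downloads. Includes readers for GWAS-Catalog-style association
    tables, SNP-by-population frequency matrices, population phenotype
    panels, and allele-frequency extraction from multi-sample VCFs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    vcfR,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
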