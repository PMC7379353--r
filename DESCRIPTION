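Package: haplomask
Title: Masked Data Analysis for Genotype Imputation Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses genotype imputation quality by masked data analysis:
    reads and writes haplotype panels in fastPHASE '.inp' and VCF formats,
    generates non-repeating sets of genotype or whole-SNP masks, counts the
    discordance between imputed and true genotypes over the masked cells, and
    selects imputation model parameters (e.g. the haplotype-cluster count of
    cluster-based imputers) by minimum-error or elbow criteria. Also provides
    the population-genetic utilities used to prepare panels for downstream
    haplotype-based selection scans: allele frequencies by population,
    Plink-style variant filters (minor allele frequency, Hardy-Weinberg exact
    test, call rate, positional duplicates), and Reynolds genetic distances.
    Includes baseline imputers, an adapter for external imputation programs,
    and a Balding-Nichols / haplotype-mosaic simulator so the whole workflow
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
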