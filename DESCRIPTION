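Package: regionepi
Title: Region-Region Interaction Testing for Case-Control GWAS via
    Linkage Disequilibrium Contrast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistical interaction (epistasis) between pairs of
    genomic regions in case-control genome-wide association studies. Each
    cross-region SNP pair is scored with a composite linkage-disequilibrium
    contrast statistic; the full correlation matrix of those pair statistics
    is derived analytically from fourth- and second-order moments of the
    genotype codes; and the minimum pair-level p-value is converted into a
    region-level p-value under a multivariate normal null. Includes readers
    for PLINK binary and plain-text genotypes, region construction from
    screened candidate SNP pairs, and a simulation harness for type-I-error
    and power experiments under an epistatic relative-risk disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
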