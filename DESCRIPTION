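Package: tagarray
Title: Cross-Population Tag SNP Selection, Array Assembly and Genotyping QC
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing and validating custom genome-wide
    genotyping arrays. Implements cross-population greedy tag-SNP selection
    over pairwise linkage-disequilibrium (r-squared), tiered non-redundant
    array assembly with minor-allele-count and region content filters,
    reference-panel coverage evaluation (max-r2 and mean-r2 curves at MAF
    cutoffs), and a genotyping quality-control battery: trio Mendelian
    consistency (parent-parent-child heritability), duplicate and
    reference-panel genotype concordance, imputation INFO scoring, and
    masked-SNP imputation accuracy.  A seeded synthetic-panel generator
    produces multi-population haplotype panels with block LD structure,
    trios with controlled Mendelian-error injection, duplicate pairs, and
    imputation posteriors, so the full pipeline is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
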