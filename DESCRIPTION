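Package: mmclone
Title: Clonality and Phylogeny Analysis of Multiple Meningiomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the clonal origin of multiple spatially
    separated meningiomas in a single patient from per-lesion somatic
    SNV/INDEL and copy-number call sets. Implements post-calling variant
    filters (population allele frequency, functional impact, contamination),
    arm-level copy-number and loss-of-heterozygosity event calling, shared
    versus private alteration partitioning, NF2-loss molecular subtyping,
    monoclonal versus independent origin classification, clonal-fraction
    estimation from variant allele fractions and from minor-allele fractions
    on LOH segments, and per-patient neighbor-joining phylogenies from binary
    alteration matrices. Includes a simulator for multi-lesion somatic call
    sets with known clonal ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
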