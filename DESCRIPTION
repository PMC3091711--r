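Package: paralogon
Title: Dating and Dissecting Gene-Family Expansions from Duplicate Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the expansion of a plant gene family at a
    single locus: codon-aware pairwise alignment and four-fold degenerate
    transversion (4DTV) dating of duplicate gene copies, k-mer self-comparison
    and chaining to delimit tandem and segmental duplication blocks, LTR
    retrotransposon insertion dating, detection of recombinant (chimeric)
    paralogues from diagnostic-site distributions, quantification of
    complementary promoter degeneration under the
    duplication-degeneration-complementation model, and copy-specific qPCR
    expression analysis (efficiency QC, delta-delta-Ct, fixed-effects ANOVA
    with Student-Newman-Keuls letter grouping). A bundled sequence-family
    evolution simulator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
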