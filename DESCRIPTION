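Package: gutcrest
Title: Insertion Mapping, Penetrance Thresholds and Expression Screens for an
    Enteric Neural Crest Mouse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a transgenic insertional mouse model of
    male-biased aganglionic megacolon (a Hirschsprung disease model). Infers
    the architecture of a transgene concatemer insertion (target-site
    duplication, breakpoints, per-unit copy number, total size) from
    paired-end whole-genome alignments; models megacolon penetrance as a
    threshold ("tipping point") on the ganglionic fraction of colon length;
    quantifies enteric neural crest cell migration tracks and explant
    invasion with circular statistics; and runs a negative-binomial
    differential-expression screen with consensus filtering, sex-chromosome
    and insertion-proximity candidate ranking, and hypergeometric term
    enrichment. Ships synthetic-data generators with recorded ground truth
    for every input, plus fixtures transcribed from the study's summary
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
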