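Package: somaticsieve
Title: Consensus Filtering and Mutational-Landscape Analysis of Tumor/Normal Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Consolidates somatic variant calls from multiple tumor/normal
    callers into a filtered mutation set using a multi-caller consensus
    cascade (caller support, tumor read evidence, germline allele-fraction,
    tumor-germline fraction gap, cohort and external germline panels,
    population allele frequency, and a coding/splice restriction), classifies
    variant consequences against gene models, profiles mutation burden and
    the six-class / trinucleotide substitution spectrum including the
    NpCpG deamination signature, and computes cohort-level recurrence and
    contingency statistics. Ships a fully self-contained synthetic
    tumor/normal cohort simulator with a known truth set so the whole
    pipeline can be exercised and benchmarked without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
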