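Package: bootDTU
Title: Differential Transcript Usage Calling with Bootstrap Reproducibility Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls differential transcript usage (DTU) between two conditions
    directly from transcript abundance estimates, with or without bootstrapped
    quantification iterations (inferential replicates). Gene-level and
    transcript-level G-tests of independence are run on replicate-summed
    counts, corrected by Benjamini-Hochberg FDR, and filtered by a
    proportion-difference effect size. Two reproducibility filters screen the
    provisional calls: quantification reproducibility over random bootstrap
    draws and inter-replicate reproducibility over cross-condition replicate
    pairs. Includes readers for Salmon and Kallisto quantifications and GTF or
    TSV transcript-to-gene maps, a negative-binomial count simulator with
    multinomial bootstrap resampling and isoform-swap DTU injection for
    benchmarking, and sensitivity/FDR/MCC scoring against the injected truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    rtracklayer,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
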