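Package: cryosig
Title: Comparative Genomic Signatures of Cold Adaptation in Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting cold-adaptation signatures
    in closely related prokaryotic genomes, motivated by comparative analyses
    of haloarchaea from polar and deep-earth hypersaline environments. Reads
    genome assemblies (FASTA) with PROKKA-style GFF3 annotations; applies
    assembly quality control and average amino-acid identity deduplication;
    computes per-genome compositional traits (element-wise G+C content,
    codon-position GC1/GC2/GC3, amino-acid composition, coding density),
    genome-scale protein flexibility and isoelectric point; performs
    pangenome rarefaction with Heaps'-law openness fitting and gene-frequency
    partitioning; and compares genome groups with Wilcoxon rank-sum tests,
    Benjamini-Hochberg adjustment, Bray-Curtis PERMANOVA and NMDS. Ships a
    synthetic-genome generator with programmed group contrasts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
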