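Package: ddradscan
Title: Sex-Linked Region Discovery and Windowed Population Statistics from
    ddRAD-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for coverage-based discovery of sex-linked genomic regions
    from double-digest RAD sequencing (ddRAD-seq). Predicts ddRAD loci by
    in-silico double restriction digestion of a genome assembly with size
    selection, builds a fragments-by-samples table of high-quality read
    mappings from per-sample alignments, applies covered-fraction and
    sample-retention filters, normalizes by per-sample library size, and
    tests each fragment for male/female coverage differences with two-sample
    Monte Carlo (permutation) tests under Benjamini-Hochberg false discovery
    rate control, merging contiguous significant fragments into candidate
    sex regions. Also provides missing-data-aware windowed nucleotide
    diversity (pi), divergence (dxy) and Hudson's Fst over diploid genotype
    matrices, and a synthetic-data module (genomes with planted restriction
    maps, negative-binomial count tables with planted sex effects,
    Balding-Nichols structured genotypes) so every stage can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
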