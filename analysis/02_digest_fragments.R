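#!/usr/bin/env Rscript
# Stage 2: in-silico double digestion of the simulated genome.
#
# Reads results/sim/genome.fa, predicts NsiI/MspI ddRAD fragments with
# the standard size selection (<= 613 bp, mixed ends only) and checks
# the prediction against the generator's ground truth.

suppressPackageStartupMessages(library(ddradscan))
out <- "results"
genome <- file.path(out, "sim", "genome.fa")
if (!file.exists(genome))
  stop("run analysis/01_simulate_data.R first", call. = FALSE)

frags <- predict_fragments(genome)
write_fragments_bed(frags, file.path(out, "fragments.bed"))
write.table(frags, file.path(out, "fragments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(out, "sim", "true_fragments.tsv"),
                    stringsAsFactors = FALSE)
same <- identical(frags[c("chrom", "start", "end")],
                  truth[c("chrom", "start", "end")])
message(sprintf("predicted %d ddRAD fragments (median %d bp)",
                nrow(frags), as.integer(median(frags$length))))
message(sprintf("exact match with the planted ground truth: %s", same))
if (!same) stop("digestion disagrees with the planted map", call. = FALSE)
message("fragment BED written to ", file.path(out, "fragments.bed"))
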