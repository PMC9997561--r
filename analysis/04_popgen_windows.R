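#!/usr/bin/env Rscript
# Stage 4: windowed population statistics over the simulated river
# populations.
#
# Loads the VCF written by stage 1, removes sites genotyped in fewer
# than 90% of samples, and computes pi per population plus dxy and
# Hudson's Fst per population pair in 10 kb windows (ratio of summed
# components, pairwise deletion of missing alleles).

suppressPackageStartupMessages(library(ddradscan))
vcf <- "results/sim/genotypes.vcf"
if (!file.exists(vcf))
  stop("run analysis/01_simulate_data.R first", call. = FALSE)

pops <- read.delim("results/sim/populations.tsv",
                   stringsAsFactors = FALSE)
gm <- read_genotypes_vcf(vcf, pops)
filt <- filter_sites_by_presence(gm, 0.9)
message(sprintf("site-presence filter removed %d of %d sites",
                attr(filt, "n_removed"), nrow(gm$allele1)))

win <- popgen_windows(filt, window_size = 10000)
write.table(win, "results/popgen_windows.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

summarize <- function(stat) {
  w <- win[win$statistic == stat, ]
  agg_n <- tapply(w$numerator, w$pop, sum)
  agg_d <- tapply(w$denominator, w$pop, sum)
  sprintf("%s: %s", stat,
          paste(sprintf("%s=%.4f", names(agg_n), agg_n / agg_d),
                collapse = "  "))
}
message(summarize("pi"))
message(summarize("dxy"))
message(summarize("fst"))
message("window table written to results/popgen_windows.tsv")
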