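#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs every later stage consumes.
#
# Three bundles are produced under results/sim/:
#   * a 2-chromosome genome (50 kb each) with a planted NsiI/MspI
#     restriction map, plus the ground-truth fragment list;
#   * a 2,000-fragment x 120-sample (64 M / 56 F) raw count table with
#     20 planted male-specific and 20 planted female-doubled fragments;
#   * 10,000 biallelic sites for the three river populations
#     (Halda 39 / Jamuna 38 / Padma 43) at Balding-Nichols Fst 0.1 with
#     10% missing genotypes, written as a VCF plus a population file.

suppressPackageStartupMessages(library(ddradscan))
seed <- 42L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating genome with planted restriction map ...")
gen <- simulate_genome(n_chrom = 2, chrom_len = 50000, seed = seed)
Biostrings::writeXStringSet(gen$sequences, file.path(out, "genome.fa"))
write.table(gen$fragments, file.path(out, "true_fragments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gen$sites, file.path(out, "true_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d planted sites -> %d ground-truth ddRAD fragments",
                nrow(gen$sites), nrow(gen$fragments)))

message("simulating fragment count table ...")
sim <- simulate_count_table(2000, n_male = 64, n_female = 56,
                            mean_depth = 20,
                            planted_male_specific = 1:20,
                            planted_female_doubled = 501:520,
                            seed = seed + 1L)
write_count_tables(sim$table, file.path(out, "counts"))
write.table(sim$truth, file.path(out, "counts_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d fragments x %d samples; library sizes %s-%s",
                nrow(sim$table$counts), ncol(sim$table$counts),
                format(min(sim$table$samples$total_hq_mappings), big.mark = ","),
                format(max(sim$table$samples$total_hq_mappings), big.mark = ",")))

message("simulating river-population genotypes ...")
simg <- simulate_genotypes(10000, target_fst = 0.1, missing_rate = 0.1,
                           seed = seed + 2L)
gm <- simg$gm
ids <- colnames(gm$allele1)
gt <- matrix("./.", nrow(gm$allele1), length(ids))
called <- !is.na(gm$allele1)
gt[called] <- paste0(gm$allele1[called], "/", gm$allele2[called])
vcf <- file.path(out, "genotypes.vcf")
writeLines(c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr_sim01>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", ids), collapse = "\t"),
  vapply(seq_len(nrow(gt)), function(i)
    paste(c(gm$chrom[i], gm$pos[i], ".", "A", "G", ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), "")
), vcf)
write.table(data.frame(sample = ids, population = unname(gm$populations)),
            file.path(out, "populations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d sites x %d samples written to %s",
                nrow(gm$allele1), length(ids), vcf))
message("done; inputs under ", out)
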