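make_fragments <- function(starts, ends, chrom = "chr1") {
  data.frame(chrom = chrom, start = starts, end = ends,
             left_enzyme = "NsiI", right_enzyme = "MspI",
             length = ends - starts,
             frag_id = sprintf("f%03d", seq_along(starts)),
             stringsAsFactors = FALSE)
}

empty_aln <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), mapq = integer(0))

test_that("per-sample counting applies the mapq and overlap rules", {
  frags <- make_fragments(c(0L, 1000L), c(200L, 1600L))
  # empty stream
  res <- count_fragment_mappings(empty_aln, frags)
  expect_equal(res$counts, c(0L, 0L))
  expect_equal(res$covered_fraction, c(0, 0))
  expect_equal(res$total_hq_mappings, 0L)
  # one mapq-60 100 bp read fully inside a 200 bp fragment
  one <- data.frame(chrom = "chr1", start = 51L, end = 150L, mapq = 60L)
  res <- count_fragment_mappings(one, frags)
  expect_equal(res$counts, c(1L, 0L))
  expect_equal(res$covered_fraction, c(0.5, 0))
  # a mapq-20 read is excluded entirely, including from the library total
  low <- data.frame(chrom = "chr1", start = 51L, end = 150L, mapq = 20L)
  res <- count_fragment_mappings(low, frags)
  expect_equal(res$counts, c(0L, 0L))
  expect_equal(res$total_hq_mappings, 0L)
  # mapq exactly 30 is retained
  res <- count_fragment_mappings(transform(low, mapq = 30L), frags)
  expect_equal(res$counts, c(1L, 0L))
  # 1 bp overlap counts; the read also counts toward the library total
  edge <- data.frame(chrom = "chr1", start = 200L, end = 299L, mapq = 60L)
  res <- count_fragment_mappings(edge, frags)
  expect_equal(res$counts, c(1L, 0L))
  expect_equal(res$covered_fraction, c(1 / 200, 0))
  # records on unknown references are skipped with a warning but still
  # count toward the high-quality library size
  off <- data.frame(chrom = c("chr1", "chrZ"), start = c(1L, 1L),
                    end = c(50L, 50L), mapq = c(60L, 60L))
  expect_warning(res <- count_fragment_mappings(off, frags), "absent")
  expect_equal(res$counts, c(1L, 0L))
  expect_equal(res$total_hq_mappings, 2L)
  expect_equal(res$n_skipped, 1L)
})

test_that("secondary/supplementary/duplicate records are excluded", {
  frags <- make_fragments(0L, 200L)
  aln <- data.frame(chrom = "chr1", start = c(1L, 1L, 1L, 1L),
                    end = c(100L, 100L, 100L, 100L), mapq = 60L,
                    secondary = c(FALSE, TRUE, FALSE, FALSE),
                    supplementary = c(FALSE, FALSE, TRUE, FALSE),
                    duplicate = c(FALSE, FALSE, FALSE, TRUE))
  res <- count_fragment_mappings(aln, frags)
  expect_equal(res$counts, 1L)
  res2 <- count_fragment_mappings(aln, frags, exclude_duplicates = FALSE)
  expect_equal(res2$counts, 2L)
})

test_that("BAM counting matches a per-base pileup oracle", {
  set.seed(19)
  frags <- make_fragments(seq(0L, 4500L, by = 500L),
                          seq(0L, 4500L, by = 500L) + sample(150:450, 10))
  n_reads <- 300
  starts <- sample.int(4800, n_reads, replace = TRUE)
  reads <- data.frame(chrom = "chr1", start = starts,
                      end = starts + 99L,
                      mapq = sample(c(0L, 20L, 30L, 60L), n_reads,
                                    replace = TRUE))
  # write the same reads as SAM text, convert, and count from the BAM
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    sprintf("r%03d\t0\tchr1\t%d\t%d\t100M\t*\t0\t0\t%s\t*",
            seq_len(n_reads), sort(reads$start),
            reads$mapq[order(reads$start)], strrep("A", 100))
  ), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  res_bam <- count_fragment_mappings(bam, frags)
  res_df <- count_fragment_mappings(reads, frags)
  oracle <- oracle_fragment_counts(reads, frags)
  expect_equal(res_bam$counts, oracle$counts)
  expect_equal(res_bam$covered_fraction, oracle$covered_fraction)
  expect_equal(res_df$counts, oracle$counts)
  expect_equal(res_df$covered_fraction, oracle$covered_fraction)
  expect_equal(res_bam$total_hq_mappings, sum(reads$mapq >= 30))
})

test_that("coverage and sample-retention filters follow the design rules", {
  set.seed(3)
  n_f <- 30; n_s <- 120
  frags <- make_fragments(seq(0L, by = 300L, length.out = n_f),
                          seq(0L, by = 300L, length.out = n_f) + 200L)
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:n_s),
    sex = rep(c("M", "F"), length.out = n_s),
    population = "r1",
    total_hq_mappings = rep(1e6, n_s)
  )
  counts <- matrix(rpois(n_f * n_s, 20), n_f, n_s)
  covered <- matrix(1, n_f, n_s)
  covered[1, 1:71] <- 0.3          # fragment 1 survives in 49 samples
  covered[2, 1] <- 0.4             # single masked pair
  covered[3, 2] <- 0.5             # exactly at threshold: survives
  tbl <- fragment_count_table(frags, samples, counts, covered)
  filt <- apply_filters(tbl, coverage_threshold = 0.5, min_samples = 50)
  expect_false("f001" %in% filt$fragments$frag_id)  # 49 < 50 dropped
  expect_true("f002" %in% filt$fragments$frag_id)
  expect_false(filt$surviving["f002", "s001"])
  expect_true(filt$surviving["f003", "s002"])
  expect_equal(filt$report$n_fragments_dropped, 1L)
  expect_equal(filt$report$n_fragments_kept, n_f - 1L)
  # all pairs fully covered: nothing changes
  tbl2 <- fragment_count_table(frags, samples, counts,
                               matrix(1, n_f, n_s))
  filt2 <- apply_filters(tbl2)
  expect_equal(filt2$counts, tbl2$counts)
  expect_equal(filt2$report$n_fragments_dropped, 0L)
  # impossible configuration
  expect_error(apply_filters(tbl, min_samples = 200), "exceeds")
})

test_that("filtering is monotone in its thresholds", {
  sim <- simulate_count_table(150, n_male = 20, n_female = 20,
                              coverage_noise = 0.3, seed = 21)
  kept <- function(cov, ms)
    apply_filters(sim$table, coverage_threshold = cov,
                  min_samples = ms)$fragments$frag_id
  lax <- kept(0.3, 10)
  expect_true(all(kept(0.5, 10) %in% lax))
  expect_true(all(kept(0.3, 30) %in% lax))
  expect_true(all(kept(0.7, 35) %in% kept(0.5, 30)))
})

test_that("normalization is per-million, scale-invariant and validated", {
  frags <- make_fragments(c(0L, 300L), c(200L, 500L))
  samples <- data.frame(sample_id = c("a", "b"), sex = c("M", "F"),
                        population = "r1",
                        total_hq_mappings = c(1e6, 2e6))
  counts <- matrix(c(10, 4, 30, 8), 2, 2)
  tbl <- fragment_count_table(frags, samples, counts,
                              matrix(1, 2, 2))
  norm <- normalize_counts(tbl)
  expect_equal(norm$values[, "a"], c(f001 = 10, f002 = 4))
  expect_equal(norm$values[, "b"], c(f001 = 15, f002 = 4))
  # element-wise oracle on a random table
  set.seed(8)
  sim <- simulate_count_table(50, n_male = 6, n_female = 6, seed = 8)
  nt <- normalize_counts(sim$table)
  expect_equal(nt$values,
               sim$table$counts /
                 rep(sim$table$samples$total_hq_mappings,
                     each = nrow(sim$table$counts)) * 1e6)
  # doubling one sample's counts and library size leaves its column fixed
  tbl2 <- tbl
  tbl2$counts[, "a"] <- tbl$counts[, "a"] * 2
  tbl2$samples$total_hq_mappings[1] <- tbl$samples$total_hq_mappings[1] * 2
  expect_equal(normalize_counts(tbl2)$values[, "a"], norm$values[, "a"])
  # zero library size names the offending sample
  tbl3 <- tbl
  tbl3$samples$total_hq_mappings[2] <- 0
  expect_error(normalize_counts(tbl3), "b")
})

test_that("filter and normalize commute with fragment reordering", {
  sim <- simulate_count_table(80, n_male = 10, n_female = 10, seed = 13)
  perm <- sample(80)
  tblp <- fragment_count_table(
    sim$table$fragments[perm, ], sim$table$samples,
    sim$table$counts[perm, ], sim$table$covered_fraction[perm, ]
  )
  a <- normalize_counts(apply_filters(sim$table, min_samples = 15))
  b <- normalize_counts(apply_filters(tblp, min_samples = 15))
  expect_equal(b$values[rownames(a$values), ], a$values)
})

test_that("count tables round-trip through their TSV directory", {
  sim <- simulate_count_table(40, n_male = 8, n_female = 8,
                              coverage_noise = 0.2, seed = 17)
  dir <- tempfile()
  write_count_tables(sim$table, dir)
  back <- read_count_tables(dir)
  expect_equal(back$counts, sim$table$counts)
  expect_equal(back$covered_fraction, sim$table$covered_fraction,
               tolerance = 1e-12)
  expect_equal(back$surviving, sim$table$surviving)
  expect_equal(back$samples$total_hq_mappings,
               sim$table$samples$total_hq_mappings)
})

test_that("simulated column sums never exceed library totals", {
  for (s in 1:5) {
    sim <- simulate_count_table(100, n_male = 15, n_female = 12, seed = s)
    expect_true(all(colSums(sim$table$counts) <=
                      sim$table$samples$total_hq_mappings))
  }
})

test_that("the retention default is 90% of the smaller sex group", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:120),
                        sex = rep(c("M", "F"), c(64, 56)))
  expect_equal(min_samples_default(samples), 50L)
})
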