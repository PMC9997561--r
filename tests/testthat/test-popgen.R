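mk_gm <- function(a1, a2, pops, chrom = NULL, pos = NULL) {
  n_sites <- nrow(a1)
  if (is.null(chrom)) chrom <- rep("c1", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites)
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- sprintf("s%02d", seq_len(ncol(a1)))
  names(pops) <- colnames(a1)
  genotype_matrix(chrom, pos, a1, a2, pops)
}

test_that("site-presence filtering drops under-called sites", {
  set.seed(2)
  n_s <- 120
  a1 <- matrix(0L, 5, n_s)
  a2 <- matrix(0L, 5, n_s)
  # site 2 called in 107/120 samples (0.892 < 0.9): removed
  a1[2, 1:13] <- NA_integer_
  # site 4 called in 108/120 (0.9): kept
  a1[4, 1:12] <- NA_integer_
  gm <- mk_gm(a1, a2, rep("p1", n_s))
  filt <- filter_sites_by_presence(gm, 0.9)
  expect_equal(filt$pos, c(1L, 3L, 4L, 5L))
  expect_equal(attr(filt, "n_removed"), 1L)
  # no missing data: identity
  gm2 <- mk_gm(matrix(0L, 5, 4), matrix(1L, 5, 4), rep("p1", 4))
  expect_equal(filter_sites_by_presence(gm2)$pos, 1:5)
})

test_that("pi matches its closed forms and the all-pairs oracle", {
  # one diploid: 2 haplotypes, 10 sites, heterozygous at one site
  a1 <- matrix(0L, 10, 1)
  a2 <- matrix(0L, 10, 1)
  a2[3, 1] <- 1L
  gm <- mk_gm(a1, a2, "p1")
  pw <- pi_windows(gm, "p1", window_size = 10000)
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$numerator, 1)
  expect_equal(pw$denominator, 10)
  expect_equal(pw$value, 0.1)
  # monomorphic window
  gm0 <- mk_gm(matrix(1L, 6, 3), matrix(1L, 6, 3), rep("p1", 3))
  expect_equal(pi_windows(gm0, "p1")$value, 0)
  # random matrix with missingness against the brute-force oracle
  set.seed(77)
  sim <- simulate_genotypes(60, n_per_pop = c(A = 7, B = 5),
                            target_fst = 0.15, missing_rate = 0.25,
                            pos_spacing = 40, seed = 77)
  pw2 <- pi_windows(sim$gm, "A", window_size = 1000)
  hap <- haplotypes_of(sim$gm, "A")
  for (i in seq_len(nrow(pw2))) {
    in_win <- sim$gm$pos >= pw2$window_start[i] &
      sim$gm$pos <= pw2$window_end[i]
    o <- oracle_pi_value(hap[, in_win, drop = FALSE])
    expect_equal(pw2$numerator[i], unname(o["num"]))
    expect_equal(pw2$denominator[i], unname(o["den"]))
  }
})

test_that("dxy matches its closed form and the all-pairs oracle", {
  # two fixed populations differing at 1 of 10 sites
  a1 <- cbind(matrix(0L, 10, 2), matrix(0L, 10, 2))
  a1[4, 3:4] <- 1L
  gm <- mk_gm(a1, a1, c("A", "A", "B", "B"))
  dw <- dxy_windows(gm, "A", "B")
  expect_equal(dw$value, 0.1)
  expect_equal(dw$denominator, 10 * 16)
  # identical populations: dxy equals pooled pi site-for-site in the
  # two-haplotype-per-pop case
  set.seed(6)
  sim <- simulate_genotypes(40, n_per_pop = c(A = 6, B = 8),
                            target_fst = 0.2, missing_rate = 0.15,
                            pos_spacing = 25, seed = 6)
  dw2 <- dxy_windows(sim$gm, "A", "B", window_size = 500)
  ha <- haplotypes_of(sim$gm, "A")
  hb <- haplotypes_of(sim$gm, "B")
  for (i in seq_len(nrow(dw2))) {
    in_win <- sim$gm$pos >= dw2$window_start[i] &
      sim$gm$pos <= dw2$window_end[i]
    o <- oracle_dxy_value(ha[, in_win, drop = FALSE],
                          hb[, in_win, drop = FALSE])
    expect_equal(dw2$numerator[i], unname(o["num"]))
    expect_equal(dw2$denominator[i], unname(o["den"]))
  }
})

test_that("Hudson Fst hits its fixed points", {
  # reciprocally fixed difference with full calls
  a <- cbind(matrix(0L, 5, 4), matrix(1L, 5, 4))
  gm <- mk_gm(a, a, rep(c("A", "B"), each = 4))
  fw <- fst_windows(gm, "A", "B")
  expect_equal(fw$value, 1)
  # identical monomorphic populations contribute zeros, value undefined
  gm0 <- mk_gm(matrix(0L, 5, 6), matrix(0L, 5, 6),
               rep(c("A", "B"), each = 3))
  fw0 <- fst_windows(gm0, "A", "B")
  expect_equal(fw0$numerator, 0)
  expect_equal(fw0$denominator, 0)
  expect_true(is.na(fw0$value))
  # equal allele frequencies, large equal samples: near zero
  sim <- simulate_genotypes(1000, n_per_pop = c(A = 50, B = 50),
                            target_fst = 0, seed = 15)
  fw1 <- fst_windows(sim$gm, "A", "B", window_size = 1e6)
  expect_lt(abs(fw1$value), 0.02)
})

test_that("windowing is a ratio of sums on the fixed 10 kb grid", {
  # two sites engineered so ratio-of-sums != mean-of-ratios
  a1 <- matrix(c(0L, 0L), 2, 4)
  a2 <- matrix(c(1L, 0L), 2, 4)  # site 1: 4 alt of 8; site 2: monomorphic
  a1[2, 1] <- NA_integer_; a2[2, 1] <- NA_integer_  # site 2: 6 alleles
  a2[2, 2] <- 1L                                    # 1 alt of 6
  gm <- mk_gm(a1, a2, rep("p1", 4), pos = c(100L, 9000L))
  pw <- pi_windows(gm, "p1")
  # site 1: num 4*4=16, den C(8,2)=28; site 2: num 1*5=5, den C(6,2)=15
  expect_equal(pw$numerator, 21)
  expect_equal(pw$denominator, 43)
  expect_equal(pw$value, 21 / 43)
  expect_false(isTRUE(all.equal(pw$value, mean(c(16 / 28, 5 / 15)))))
  # window boundaries are [1, 10000], [10001, 20000], ... per chromosome
  a <- matrix(0L, 3, 2); b <- matrix(1L, 3, 2)
  gm2 <- mk_gm(a, b, rep("p1", 2), chrom = c("c1", "c1", "c2"),
               pos = c(10000L, 10001L, 5L))
  pw2 <- pi_windows(gm2, "p1")
  expect_equal(pw2$window_start, c(1L, 10001L, 1L))
  expect_equal(pw2$window_end, c(10000L, 20000L, 10000L))
  expect_equal(pw2$chrom, c("c1", "c1", "c2"))
})

test_that("pi and dxy are invariant to allele swap and sample order", {
  set.seed(9)
  sim <- simulate_genotypes(50, n_per_pop = c(A = 5, B = 6),
                            target_fst = 0.1, missing_rate = 0.2, seed = 9)
  gm <- sim$gm
  swapped <- genotype_matrix(gm$chrom, gm$pos, 1L - gm$allele1,
                             1L - gm$allele2, gm$populations)
  perm <- sample(ncol(gm$allele1))
  shuffled <- genotype_matrix(gm$chrom, gm$pos,
                              gm$allele1[, perm], gm$allele2[, perm],
                              gm$populations)
  for (g in list(swapped, shuffled)) {
    expect_equal(pi_windows(g, "A"), pi_windows(gm, "A"))
    expect_equal(dxy_windows(g, "A", "B"), dxy_windows(gm, "A", "B"))
  }
})

test_that("VCF genotypes round-trip through the loader", {
  sim <- simulate_genotypes(12, n_per_pop = c(A = 3, B = 3),
                            missing_rate = 0.2, seed = 44)
  gm <- sim$gm
  # write a minimal VCF by hand and reload it
  ids <- colnames(gm$allele1)
  gt <- matrix("./.", 12, 6)
  called <- !is.na(gm$allele1)
  gt[called] <- paste0(gm$allele1[called], "/", gm$allele2[called])
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr_sim01>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"),
    vapply(1:12, function(i)
      paste(c("chr_sim01", gm$pos[i], ".", "A", "G", ".", "PASS", ".",
              "GT", gt[i, ]), collapse = "\t"), "")
  ), vcf)
  back <- read_genotypes_vcf(vcf, data.frame(sample = ids,
                                             population = gm$populations))
  expect_equal(unname(back$allele1), unname(gm$allele1))
  expect_equal(unname(back$allele2), unname(gm$allele2))
  expect_equal(back$pos, gm$pos)
  expect_equal(pi_windows(back, "A"), pi_windows(gm, "A"))
})

test_that("popgen_windows emits the full long-format table", {
  sim <- simulate_genotypes(30, n_per_pop = c(A = 4, B = 4, C = 4),
                            target_fst = 0.05, seed = 3)
  w <- popgen_windows(sim$gm)
  expect_setequal(unique(w$statistic), c("pi", "dxy", "fst"))
  expect_equal(sum(w$statistic == "pi"), 3L)   # one window per pop
  expect_equal(sum(w$statistic == "dxy"), 3L)  # three pairs
  expect_equal(sum(w$statistic == "fst"), 3L)
})
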