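# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings) so agreement is informative.

iupac_expand <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# exhaustive sliding-window scan; returns 0-based match starts
oracle_find_sites <- function(sequence, motif) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  n <- nchar(sequence)
  L <- nchar(motif)
  if (n < L) return(integer(0))
  if (!grepl("[^ACGT]", motif)) {
    # unambiguous motif: compare every window by plain string equality
    wins <- substring(sequence, seq_len(n - L + 1L), L:n)
    return(which(wins == motif) - 1L)
  }
  seq_chars <- strsplit(sequence, "")[[1]]
  motif_chars <- strsplit(motif, "")[[1]]
  allowed <- lapply(motif_chars, function(m)
    strsplit(iupac_expand[[m]], "")[[1]])
  hits <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(seq_chars[i + j - 1L] %in% allowed[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# manual double-digest interval construction from two site lists
oracle_fragments <- function(sequence, motif_a, off_a, motif_b, off_b,
                             min_len = 0, max_len = 613,
                             different_ends = TRUE) {
  cuts_a <- oracle_find_sites(sequence, motif_a) + off_a
  cuts_b <- oracle_find_sites(sequence, motif_b) + off_b
  cuts <- data.frame(pos = c(cuts_a, cuts_b),
                     enz = c(rep("A", length(cuts_a)),
                             rep("B", length(cuts_b))))
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]
  out <- NULL
  if (nrow(cuts) >= 2L) {
    for (i in seq_len(nrow(cuts) - 1L)) {
      len <- cuts$pos[i + 1L] - cuts$pos[i]
      if (different_ends && cuts$enz[i] == cuts$enz[i + 1L]) next
      if (len < min_len || len > max_len) next
      out <- rbind(out, data.frame(start = cuts$pos[i],
                                   end = cuts$pos[i + 1L]))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0))
  else out
}

# literal BH step-up: sort, q_i = min_{j>=i} p_(j) m / j, clip, unsort
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# per-base pileup oracle for one sample's fragment counts and coverage;
# reads: data.frame(chrom, start, end, mapq) 1-based inclusive
oracle_fragment_counts <- function(reads, fragments, mapq_min = 30) {
  reads <- reads[reads$mapq >= mapq_min, , drop = FALSE]
  counts <- integer(nrow(fragments))
  covered <- numeric(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    fs <- fragments$start[i] + 1L   # to 1-based inclusive
    fe <- fragments$end[i]
    r <- reads[reads$chrom == fragments$chrom[i] &
                 reads$start <= fe & reads$end >= fs, , drop = FALSE]
    counts[i] <- nrow(r)
    base_hit <- rep(FALSE, fe - fs + 1L)
    for (j in seq_len(nrow(r))) {
      a <- max(fs, r$start[j]) - fs + 1L
      b <- min(fe, r$end[j]) - fs + 1L
      base_hit[a:b] <- TRUE
    }
    covered[i] <- sum(base_hit) / (fe - fs + 1L)
  }
  list(counts = counts, covered_fraction = covered)
}

# exhaustive two-sample permutation p over all label assignments
oracle_enum_perm_p <- function(values, n_male) {
  n <- length(values)
  sets <- utils::combn(n, n_male)
  obs <- abs(mean(values[seq_len(n_male)]) -
               mean(values[-seq_len(n_male)]))
  stats <- apply(sets, 2L, function(ix)
    abs(mean(values[ix]) - mean(values[-ix])))
  mean(stats >= obs - 1e-12)
}

# brute-force within-population pi over allele pairs, per window;
# alleles: 2n x sites matrix (rows = haplotypes) with NA for missing
oracle_pi_value <- function(alleles) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(alleles))) {
    a <- unname(alleles[, s])
    a <- a[!is.na(a)]
    if (length(a) < 2L) next
    for (i in seq_len(length(a) - 1L))
      for (j in (i + 1L):length(a)) {
        num <- num + (a[i] != a[j])
        den <- den + 1
      }
  }
  c(num = num, den = den)
}

# brute-force cross-population dxy over allele pairs
oracle_dxy_value <- function(alleles_a, alleles_b) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(alleles_a))) {
    a <- unname(alleles_a[, s]); a <- a[!is.na(a)]
    b <- unname(alleles_b[, s]); b <- b[!is.na(b)]
    for (x in a) for (y in b) {
      num <- num + (x != y)
      den <- den + 1
    }
  }
  c(num = num, den = den)
}

# stack a genotype_matrix's two allele matrices into haplotype rows for
# the oracles above, restricted to one population
haplotypes_of <- function(gm, population) {
  ix <- names(gm$populations)[gm$populations == population]
  rbind(t(gm$allele1[, ix, drop = FALSE]),
        t(gm$allele2[, ix, drop = FALSE]))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
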