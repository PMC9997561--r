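#' Simulate a genome with a planted restriction map
#'
#' Generates random chromosome sequences with recognition sites of two
#' enzymes planted at Poisson spacing, together with the exact fragment
#' list the digestion predictor should recover. Background bases that
#' happen to spell out a recognition motif (including across
#' motif/background junctions) are mutated away, so the planted map is
#' the complete site map.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len Length of each chromosome in bp (default 50000).
#' @param site_rate_per_kb Named numeric: expected planted sites per kb
#'   for each enzyme, names matching the enzyme names (defaults: NsiI
#'   0.4, MspI 2 -- a 6-cutter/4-cutter density ratio).
#' @param enzyme_a,enzyme_b [restriction_enzyme()] objects.
#' @param min_len,max_len,ends_rule Size selection and ends rule used for
#'   the ground-truth fragment list (defaults as in
#'   [predict_fragments()]).
#' @param seed Integer RNG seed; output is a deterministic function of
#'   the seed.
#' @return List with `sequences` ([Biostrings::DNAStringSet]), `sites`
#'   (data.frame `chrom`, `pos` 0-based, `enzyme`) and `fragments` (the
#'   ground-truth fragment table, same shape as [predict_fragments()]
#'   output).
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_len = 50000L,
                            site_rate_per_kb = c(NsiI = 0.4, MspI = 2),
                            enzyme_a = ddrad_enzyme("NsiI"),
                            enzyme_b = ddrad_enzyme("MspI"),
                            min_len = 0L, max_len = 613L,
                            ends_rule = c("different_enzymes", "any"),
                            seed = 1L) {
  ends_rule <- match.arg(ends_rule)
  stopifnot(n_chrom >= 1L, chrom_len > 0L)
  enzymes <- list(enzyme_a, enzyme_b)
  names(enzymes) <- c(enzyme_a$name, enzyme_b$name)
  rates <- site_rate_per_kb[names(enzymes)]
  rates[is.na(rates)] <- 0
  set.seed(as.integer(seed) %% 2147483647L)

  gap <- max(vapply(enzymes, function(e) nchar(e$recognition), 0L)) + 1L
  seqs <- character(n_chrom)
  all_sites <- vector("list", n_chrom)
  chroms <- sprintf("chr_sim%02d", seq_len(n_chrom))
  for (k in seq_len(n_chrom)) {
    sites <- data.frame(pos = integer(0), enzyme = character(0),
                        stringsAsFactors = FALSE)
    for (e in names(enzymes)) {
      motif_len <- nchar(enzymes[[e]]$recognition)
      n_sites <- rpois(1L, rates[e] * chrom_len / 1000)
      if (n_sites > 0L) {
        pos <- sort(sample.int(chrom_len - motif_len, n_sites))
        sites <- rbind(sites, data.frame(pos = pos, enzyme = e,
                                         stringsAsFactors = FALSE))
      }
    }
    sites <- sites[order(sites$pos), , drop = FALSE]
    # enforce spacing so planted motifs never overlap
    if (nrow(sites) > 1L) {
      keep <- c(TRUE, diff(sites$pos) >= gap)
      while (!all(keep)) {
        sites <- sites[keep, , drop = FALSE]
        keep <- c(TRUE, diff(sites$pos) >= gap)
      }
    }
    bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    protected <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(sites))) {
      e <- enzymes[[sites$enzyme[i]]]
      span <- sites$pos[i] + seq_len(nchar(e$recognition))
      bases[span] <- strsplit(e$recognition, "")[[1]]
      protected[span] <- TRUE
    }
    # mutate away accidental motifs outside the planted map
    for (iter in 1:200) {
      seq_str <- paste(bases, collapse = "")
      bad <- integer(0)
      for (e in names(enzymes)) {
        found <- find_sites(seq_str, enzymes[[e]])
        planted <- sites$pos[sites$enzyme == e]
        extra <- setdiff(found, planted)
        motif_len <- nchar(enzymes[[e]]$recognition)
        for (x in extra) {
          span <- x + seq_len(motif_len)
          free <- span[!protected[span]]
          if (length(free) > 0L) bad <- c(bad, free[ceiling(length(free) / 2)])
        }
      }
      if (length(bad) == 0L) break
      for (b in unique(bad))
        bases[b] <- sample(setdiff(c("A", "C", "G", "T"), bases[b]), 1L)
    }
    seqs[k] <- paste(bases, collapse = "")
    if (nrow(sites) > 0L) sites$chrom <- chroms[k]
    all_sites[[k]] <- sites
  }
  names(seqs) <- chroms
  sites <- do.call(rbind, all_sites[vapply(all_sites, nrow, 0L) > 0])
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        enzyme = character(0), stringsAsFactors = FALSE)
  sites <- sites[, c("chrom", "pos", "enzyme")]

  # ground-truth fragments from the planted map, using the same interval
  # conventions as the predictor
  truth <- lapply(sort(chroms), function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    offs <- vapply(enzymes, `[[`, 0L, "cut_offset")
    cuts <- data.frame(pos = s$pos + offs[s$enzyme], enzyme = s$enzyme,
                       stringsAsFactors = FALSE)
    fragments_from_cuts(cuts, ch)
  })
  frags <- do.call(rbind, truth)
  if (is.null(frags))
    frags <- fragments_from_cuts(data.frame(pos = integer(0),
                                            enzyme = character(0)), "")
  if (ends_rule == "different_enzymes")
    frags <- frags[frags$left_enzyme != frags$right_enzyme, , drop = FALSE]
  frags <- frags[frags$length >= min_len & frags$length <= max_len, ,
                 drop = FALSE]
  rownames(frags) <- NULL
  if (nrow(frags) > 0L)
    frags$frag_id <- sprintf("%s-%s_%05d", frags$left_enzyme,
                             frags$right_enzyme, seq_len(nrow(frags)))
  else frags$frag_id <- character(0)

  list(sequences = Biostrings::DNAStringSet(seqs), sites = sites,
       fragments = frags)
}

# proportional allocation with largest remainders, so default sex-group
# sizes reproduce the study's river split exactly at n = 120
allocate_populations <- function(n, pops = c(Halda = 39, Jamuna = 38,
                                             Padma = 43)) {
  share <- pops / sum(pops) * n
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(pops), times = base)
}

#' Simulate a fragments-by-samples count table with planted sex effects
#'
#' Emulates the statistical structure of ddRAD per-fragment mapping
#' counts: per-sample library-size factors (log-normal), per-fragment
#' relative abundances (gamma), negative-binomial counts, and planted
#' sex-linked effects -- `male_specific` fragments have exactly zero
#' counts in every female, `female_doubled` fragments have the female
#' mean multiplied by 2. Covered fractions are 1 where the count is
#' positive and 0 otherwise (optionally perturbed so the coverage filter
#' is exercised on non-zero counts too).
#'
#' @param n_fragments Number of fragments.
#' @param n_male,n_female Sample sizes (defaults 64 and 56, the study
#'   design this generator emulates).
#' @param mean_depth Baseline expected count per fragment per sample
#'   (default 20).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param library_size_cv Coefficient of variation of the per-sample
#'   library factor (default 0.2).
#' @param gamma_shape Shape of the per-fragment abundance distribution
#'   (default 4; mean fixed at 1).
#' @param planted_male_specific,planted_female_doubled Integer vectors of
#'   fragment indices carrying each planted effect.
#' @param coverage_noise Probability that a positive-count pair gets a
#'   covered fraction drawn below the usual 0.5 threshold (default 0).
#' @param seed Integer RNG seed.
#' @return List with `table` (a `fragment_count_table`) and `truth`
#'   (data.frame `frag_id`, `effect`).
#' @export
simulate_count_table <- function(n_fragments, n_male = 64L, n_female = 56L,
                                 mean_depth = 20, dispersion = 5,
                                 library_size_cv = 0.2, gamma_shape = 4,
                                 planted_male_specific = integer(0),
                                 planted_female_doubled = integer(0),
                                 coverage_noise = 0, seed = 1L) {
  stopifnot(n_fragments >= 1L, n_male >= 1L, n_female >= 1L,
            mean_depth > 0, dispersion > 0, library_size_cv >= 0,
            all(planted_male_specific %in% seq_len(n_fragments)),
            all(planted_female_doubled %in% seq_len(n_fragments)),
            length(intersect(planted_male_specific,
                             planted_female_doubled)) == 0L)
  set.seed(as.integer(seed) %% 2147483647L)
  n_s <- n_male + n_female
  sex <- c(rep("M", n_male), rep("F", n_female))
  samples <- data.frame(
    sample_id = sprintf("%s%03d", sex, c(seq_len(n_male), seq_len(n_female))),
    sex = sex,
    population = allocate_populations(n_s),
    stringsAsFactors = FALSE
  )
  lens <- sample(100:613, n_fragments, replace = TRUE)
  starts <- cumsum(c(0L, lens[-n_fragments] + 200L))
  fragments <- data.frame(
    chrom = "chr_sim01", start = starts, end = starts + lens,
    left_enzyme = "NsiI", right_enzyme = "MspI", length = lens,
    frag_id = sprintf("sim_%05d", seq_len(n_fragments)),
    stringsAsFactors = FALSE
  )
  sdlog <- sqrt(log(1 + library_size_cv^2))
  lib <- rlnorm(n_s, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  rel <- rgamma(n_fragments, shape = gamma_shape, rate = gamma_shape)
  mu <- outer(rel * mean_depth, lib)
  is_f <- sex == "F"
  mu[planted_female_doubled, is_f] <- 2 * mu[planted_female_doubled, is_f]
  mu[planted_male_specific, is_f] <- 0
  counts <- matrix(rnbinom(length(mu), size = dispersion, mu = mu),
                   n_fragments, n_s)
  counts[planted_male_specific, is_f] <- 0L
  covered <- (counts > 0) * 1
  if (coverage_noise > 0) {
    flip <- matrix(runif(length(counts)) < coverage_noise,
                   n_fragments, n_s) & counts > 0
    covered[flip] <- runif(sum(flip), 0, 0.49)
  }
  extra <- rpois(n_s, 0.25 * colSums(counts))
  samples$total_hq_mappings <- colSums(counts) + extra
  effect <- rep("none", n_fragments)
  effect[planted_male_specific] <- "male_specific"
  effect[planted_female_doubled] <- "female_doubled"
  list(
    table = fragment_count_table(fragments, samples, counts, covered),
    truth = data.frame(frag_id = fragments$frag_id, effect = effect,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate structured diploid genotypes (Balding-Nichols)
#'
#' Draws ancestral allele frequencies Uniform(0.05, 0.95), population
#' frequencies from the Balding-Nichols beta distribution with the given
#' target Fst, diploid genotypes binomially, and missingness i.i.d. per
#' genotype.
#'
#' @param n_sites Number of biallelic sites.
#' @param n_per_pop Named integer vector of samples per population
#'   (default `c(Halda = 39, Jamuna = 38, Padma = 43)`, the study's
#'   river sample sizes).
#' @param target_fst Balding-Nichols differentiation parameter in
#'   `[0, 1)` (default 0).
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param pos_spacing Distance between consecutive sites in bp
#'   (default 100, so 10-kb windows hold ~100 sites).
#' @param chrom Chromosome name for all sites.
#' @param seed Integer RNG seed.
#' @return List with `gm` (a `genotype_matrix`) and `truth` (list of
#'   `ancestral_freq`, `pop_freq` matrix, `target_fst`).
#' @export
simulate_genotypes <- function(n_sites,
                               n_per_pop = c(Halda = 39, Jamuna = 38,
                                             Padma = 43),
                               target_fst = 0, missing_rate = 0,
                               pos_spacing = 100L, chrom = "chr_sim01",
                               seed = 1L) {
  stopifnot(n_sites >= 1L, all(n_per_pop >= 1L),
            target_fst >= 0, target_fst < 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(as.integer(seed) %% 2147483647L)
  pops <- names(n_per_pop)
  if (is.null(pops)) pops <- paste0("pop", seq_along(n_per_pop))
  p_anc <- runif(n_sites, 0.05, 0.95)
  pop_freq <- vapply(seq_along(n_per_pop), function(k) {
    if (target_fst == 0) p_anc
    else rbeta(n_sites, p_anc * (1 - target_fst) / target_fst,
               (1 - p_anc) * (1 - target_fst) / target_fst)
  }, numeric(n_sites))
  pop_freq <- matrix(pop_freq, n_sites, length(n_per_pop),
                     dimnames = list(NULL, pops))
  n_total <- sum(n_per_pop)
  a1 <- a2 <- matrix(NA_integer_, n_sites, n_total)
  populations <- character(n_total)
  ids <- character(n_total)
  col <- 0L
  for (k in seq_along(n_per_pop)) {
    for (j in seq_len(n_per_pop[k])) {
      col <- col + 1L
      a1[, col] <- rbinom(n_sites, 1L, pop_freq[, k])
      a2[, col] <- rbinom(n_sites, 1L, pop_freq[, k])
      populations[col] <- pops[k]
      ids[col] <- sprintf("%s_%03d", pops[k], j)
    }
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(n_sites * n_total) < missing_rate, n_sites, n_total)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  colnames(a1) <- colnames(a2) <- ids
  names(populations) <- ids
  gm <- genotype_matrix(rep(chrom, n_sites),
                        seq(1L, by = as.integer(pos_spacing),
                            length.out = n_sites),
                        a1, a2, populations)
  list(gm = gm, truth = list(ancestral_freq = p_anc, pop_freq = pop_freq,
                             target_fst = target_fst))
}
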