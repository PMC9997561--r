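#' Construct a diploid genotype matrix
#'
#' Container for biallelic diploid genotypes: two allele matrices (sites
#' by samples, values 0 = reference, 1 = alternate, `NA` = missing) plus
#' site coordinates and a sample-to-population map. A genotype is
#' treated as missing when either allele is uncalled.
#'
#' @param chrom Character vector of site chromosomes.
#' @param pos Integer vector of 1-based site positions, strictly
#'   increasing within each chromosome.
#' @param allele1,allele2 Integer matrices (sites x samples) with values
#'   in `{0, 1, NA}`.
#' @param populations Named character vector mapping sample id to
#'   population; names must match the matrices' column names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, allele1, allele2, populations) {
  stopifnot(is.matrix(allele1), is.matrix(allele2),
            all(dim(allele1) == dim(allele2)),
            length(chrom) == nrow(allele1), length(pos) == nrow(allele1))
  for (m in list(allele1, allele2))
    if (!all(m %in% c(0L, 1L, NA)))
      stop("allele codes must be 0, 1 or NA", call. = FALSE)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within ", ch,
           call. = FALSE)
  }
  if (is.null(colnames(allele1)))
    colnames(allele1) <- colnames(allele2) <-
      paste0("S", seq_len(ncol(allele1)))
  if (!all(colnames(allele1) %in% names(populations)))
    stop("every sample needs a population label", call. = FALSE)
  # half-called genotypes are treated as fully missing
  miss <- is.na(allele1) | is.na(allele2)
  allele1[miss] <- NA_integer_
  allele2[miss] <- NA_integer_
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         allele1 = allele1, allele2 = allele2,
         populations = populations[colnames(allele1)]),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples, populations: %s\n",
              nrow(x$allele1), ncol(x$allele1),
              paste(names(table(x$populations)), collapse = ", ")))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Loads biallelic SNP genotypes (GT field) from a VCF; multiallelic and
#' non-SNP sites are rejected with a message reporting how many were
#' dropped. Half-called genotypes become missing.
#'
#' @param path VCF path (plain or bgzip).
#' @param populations Named character vector (sample -> population), or a
#'   two-column data.frame `(sample, population)`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path, populations) {
  if (is.data.frame(populations)) {
    pops <- as.character(populations[[2]])
    names(pops) <- as.character(populations[[1]])
    populations <- pops
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  if (any(!biallelic))
    message(sum(!biallelic), " multiallelic/non-SNP site(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  chrom <- fix[biallelic, "CHROM"]
  pos <- as.integer(fix[biallelic, "POS"])
  parse_allele <- function(g, which) {
    a <- vapply(strsplit(ifelse(is.na(g), ".|.", g), "[/|]"),
                function(x) if (length(x) >= which) x[which] else ".", "")
    suppressWarnings(as.integer(ifelse(a == ".", NA, a)))
  }
  a1 <- matrix(parse_allele(gt, 1L), nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  a2 <- matrix(parse_allele(gt, 2L), nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  genotype_matrix(chrom, pos, a1, a2, populations)
}

#' Remove sites genotyped in too few samples
#'
#' Drops sites where the fraction of samples with a called (non-missing)
#' genotype is below `min_fraction`; site order is preserved.
#'
#' @param gm A `genotype_matrix`.
#' @param min_fraction Minimum presence fraction (default 0.9: sites
#'   present in fewer than 90% of samples are removed).
#' @return A filtered `genotype_matrix` with attribute `n_removed`.
#' @export
filter_sites_by_presence <- function(gm, min_fraction = 0.9) {
  stopifnot(inherits(gm, "genotype_matrix"))
  called <- !is.na(gm$allele1)
  frac <- rowMeans(called)
  keep <- frac >= min_fraction
  out <- genotype_matrix(gm$chrom[keep], gm$pos[keep],
                         gm$allele1[keep, , drop = FALSE],
                         gm$allele2[keep, , drop = FALSE],
                         gm$populations)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Per-site called-allele count (n) and alternate-allele count (c) for a
# set of sample columns.
site_allele_counts <- function(gm, samples) {
  a1 <- gm$allele1[, samples, drop = FALSE]
  a2 <- gm$allele2[, samples, drop = FALSE]
  n <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  c_alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  list(n = n, c_alt = c_alt)
}

window_of <- function(pos, window_size) (pos - 1L) %/% window_size

# Aggregate per-site numerators/denominators into windows; value is the
# ratio of summed components, NA where the denominator is zero.
aggregate_windows <- function(chrom, pos, num, den, window_size,
                              statistic, pop_label) {
  w <- window_of(pos, window_size)
  key <- paste(chrom, w, sep = "\r")
  agg_num <- tapply(num, key, sum)
  agg_den <- tapply(den, key, sum)
  agg_n <- tapply(num, key, length)
  parts <- strsplit(names(agg_num), "\r", fixed = TRUE)
  wchrom <- vapply(parts, `[`, "", 1L)
  wi <- as.integer(vapply(parts, `[`, "", 2L))
  out <- data.frame(
    chrom = wchrom,
    window_start = wi * window_size + 1L,
    window_end = (wi + 1L) * window_size,
    statistic = statistic, pop = pop_label,
    numerator = as.numeric(agg_num), denominator = as.numeric(agg_den),
    n_sites = as.integer(agg_n),
    value = ifelse(agg_den > 0, agg_num / agg_den, NA_real_),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Average pairwise difference among called alleles within one
#' population, windowed as a ratio of sums: per site the numerator is
#' the number of differing allele pairs among called alleles and the
#' denominator the number of allele pairs `choose(n, 2)`; a window's
#' value is the summed numerator over the summed denominator (never a
#' mean of per-site ratios). Missing alleles are pairwise-deleted; sites
#' with fewer than two called alleles contribute nothing. The
#' denominator counts only sites present in the matrix, so per-base
#' diversity over a region requires monomorphic sites to be included as
#' rows.
#'
#' @param gm A `genotype_matrix`.
#' @param population Population label to use.
#' @param window_size Window width in bp (default 10000); windows tile
#'   each chromosome as `[1, w], [w + 1, 2w], ...` (1-based inclusive).
#' @return Data.frame of window statistics: `chrom`, `window_start`,
#'   `window_end`, `statistic`, `pop`, `numerator`, `denominator`,
#'   `n_sites`, `value` (NA where the denominator is zero).
#' @export
pi_windows <- function(gm, population, window_size = 10000L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- names(gm$populations)[gm$populations == population]
  if (length(samples) == 0L)
    stop("no samples in population '", population, "'", call. = FALSE)
  ac <- site_allele_counts(gm, samples)
  num <- ac$c_alt * (ac$n - ac$c_alt)
  den <- ac$n * (ac$n - 1) / 2
  aggregate_windows(gm$chrom, gm$pos, num, den, window_size, "pi",
                    population)
}

#' Windowed between-population divergence (dxy)
#'
#' Average pairwise difference between alleles drawn one from each
#' population: per site the numerator counts cross-population differing
#' allele pairs and the denominator `n_A * n_B` called-allele pairs;
#' windows are ratios of sums with pairwise deletion of missing alleles.
#'
#' @inheritParams pi_windows
#' @param pop_a,pop_b Population labels.
#' @return Window data.frame as in [pi_windows()], `pop` =
#'   `"popA:popB"`.
#' @export
dxy_windows <- function(gm, pop_a, pop_b, window_size = 10000L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sa <- names(gm$populations)[gm$populations == pop_a]
  sb <- names(gm$populations)[gm$populations == pop_b]
  if (length(sa) == 0L || length(sb) == 0L)
    stop("both populations must be non-empty", call. = FALSE)
  aca <- site_allele_counts(gm, sa)
  acb <- site_allele_counts(gm, sb)
  num <- aca$c_alt * (acb$n - acb$c_alt) + (aca$n - aca$c_alt) * acb$c_alt
  den <- aca$n * acb$n
  aggregate_windows(gm$chrom, gm$pos, num, den, window_size, "dxy",
                    paste(pop_a, pop_b, sep = ":"))
}

#' Windowed Hudson's Fst
#'
#' Hudson's Fst from per-site allele frequencies with sample-size
#' correction, windowed as a ratio of averages: per site with allele
#' frequencies `p1`, `p2` and called-allele counts `n1, n2 >= 2`,
#' numerator `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) /
#' (n2 - 1)` and denominator `p1 (1 - p2) + p2 (1 - p1)`; the window
#' value is the summed numerator over the summed denominator. Sites
#' monomorphic in both populations contribute zeros to both sums; sites
#' with fewer than two called alleles in either population are skipped.
#' Negative estimates are possible and preserved.
#'
#' @inheritParams dxy_windows
#' @param estimator Only `"hudson"` is implemented.
#' @return Window data.frame as in [pi_windows()], `statistic = "fst"`.
#' @export
fst_windows <- function(gm, pop_a, pop_b, window_size = 10000L,
                        estimator = "hudson") {
  estimator <- match.arg(estimator, "hudson")
  stopifnot(inherits(gm, "genotype_matrix"))
  sa <- names(gm$populations)[gm$populations == pop_a]
  sb <- names(gm$populations)[gm$populations == pop_b]
  aca <- site_allele_counts(gm, sa)
  acb <- site_allele_counts(gm, sb)
  ok <- aca$n >= 2 & acb$n >= 2
  p1 <- ifelse(ok, aca$c_alt / aca$n, NA)
  p2 <- ifelse(ok, acb$c_alt / acb$n, NA)
  num <- ifelse(ok,
                (p1 - p2)^2 - p1 * (1 - p1) / (aca$n - 1) -
                  p2 * (1 - p2) / (acb$n - 1),
                0)
  den <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), 0)
  aggregate_windows(gm$chrom, gm$pos, num, den, window_size, "fst",
                    paste(pop_a, pop_b, sep = ":"))
}

#' Compute all windowed statistics for every population (pair)
#'
#' Convenience wrapper producing a long-format table of pi for each
#' population and dxy/Fst for each population pair.
#'
#' @param gm A `genotype_matrix`.
#' @param window_size Window width in bp (default 10000).
#' @return Long-format data.frame combining [pi_windows()],
#'   [dxy_windows()] and [fst_windows()] output.
#' @export
popgen_windows <- function(gm, window_size = 10000L) {
  pops <- sort(unique(gm$populations))
  out <- lapply(pops, function(p) pi_windows(gm, p, window_size))
  if (length(pops) > 1L) {
    pairs <- utils::combn(pops, 2L, simplify = FALSE)
    out <- c(out,
             lapply(pairs, function(pr)
               dxy_windows(gm, pr[1L], pr[2L], window_size)),
             lapply(pairs, function(pr)
               fst_windows(gm, pr[1L], pr[2L], window_size)))
  }
  do.call(rbind, out)
}
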