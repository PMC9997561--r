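#' Count high-quality mappings per fragment for one sample
#'
#' Counts, for each predicted fragment, the alignments that overlap it by
#' at least 1 bp after mapping-quality filtering, and the fraction of the
#' fragment's bases covered by at least one retained alignment. Unmapped,
#' secondary, supplementary and (by default) duplicate-marked records are
#' excluded. The sample's total number of retained high-quality mappings
#' (across the whole genome, not only fragments) is recorded for
#' library-size normalization.
#'
#' @param alignments Either a path to a coordinate-sorted indexed BAM
#'   file, or a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive reference interval of the alignment) and `mapq`, plus
#'   optional logical columns `secondary`, `supplementary`, `duplicate`.
#' @param fragments Fragment table from [predict_fragments()].
#' @param mapq_min Minimum mapping quality (default 30).
#' @param exclude_duplicates Drop duplicate-marked records (default TRUE).
#' @return A list with `counts` and `covered_fraction` (numeric vectors
#'   over fragments, in fragment order), `total_hq_mappings`, and
#'   `n_skipped` (retained records on references absent from the fragment
#'   table).
#' @export
count_fragment_mappings <- function(alignments, fragments, mapq_min = 30,
                                    exclude_duplicates = TRUE) {
  if (nrow(fragments) == 0L) stop("fragment set is empty", call. = FALSE)
  aln <- load_alignments(alignments, exclude_duplicates)
  keep <- !is.na(aln$mapq) & aln$mapq >= mapq_min
  aln <- aln[keep, , drop = FALSE]
  total_hq <- nrow(aln)

  known <- aln$chrom %in% fragments$chrom
  n_skipped <- sum(!known)
  if (n_skipped > 0L)
    warning(n_skipped, " retained mapping(s) on references absent from the ",
            "fragment set", call. = FALSE)
  aln <- aln[known, , drop = FALSE]

  counts <- integer(nrow(fragments))
  covered <- numeric(nrow(fragments))
  for (chrom in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == chrom)
    # fragments are 0-based half-open; IRanges are 1-based inclusive
    frag_ir <- IRanges::IRanges(start = fragments$start[fi] + 1L,
                                end = fragments$end[fi])
    ai <- aln$chrom == chrom
    if (!any(ai)) next
    read_ir <- IRanges::IRanges(start = aln$start[ai], end = aln$end[ai])
    counts[fi] <- IRanges::countOverlaps(frag_ir, read_ir, minoverlap = 1L)
    cov <- IRanges::coverage(read_ir,
                             width = max(max(fragments$end[fi]),
                                         max(aln$end[ai])))
    covered_bases <- sum(IRanges::Views(cov > 0L, frag_ir))
    covered[fi] <- covered_bases / fragments$length[fi]
  }
  list(counts = counts, covered_fraction = covered,
       total_hq_mappings = total_hq, n_skipped = n_skipped)
}

# Normalize alignment input to a data.frame(chrom, start, end, mapq) of
# primary mapped records.
load_alignments <- function(alignments, exclude_duplicates) {
  if (is.character(alignments)) {
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = if (exclude_duplicates) FALSE else NA
    )
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
    ga <- GenomicAlignments::readGAlignments(alignments, param = param)
    return(data.frame(
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      start = BiocGenerics::start(ga), end = BiocGenerics::end(ga),
      mapq = S4Vectors::mcols(ga)$mapq, stringsAsFactors = FALSE
    ))
  }
  stopifnot(is.data.frame(alignments),
            all(c("chrom", "start", "end", "mapq") %in% names(alignments)))
  aln <- alignments
  drop <- rep(FALSE, nrow(aln))
  for (col in c("secondary", "supplementary", "unmapped"))
    if (col %in% names(aln)) drop <- drop | aln[[col]]
  if (exclude_duplicates && "duplicate" %in% names(aln))
    drop <- drop | aln$duplicate
  aln[!drop, c("chrom", "start", "end", "mapq"), drop = FALSE]
}

#' Build a fragments-by-samples count table
#'
#' Runs [count_fragment_mappings()] for every sample in the sample sheet
#' and assembles the raw-count, covered-fraction and surviving matrices.
#'
#' @param fragments Fragment table from [predict_fragments()].
#' @param samples Sample sheet data.frame with columns `sample_id`, `sex`
#'   (`"M"`/`"F"`) and `population`; a `bam` column may give per-sample
#'   BAM paths if `alignments` is not supplied.
#' @param alignments Named list (by `sample_id`) of alignment inputs as
#'   accepted by [count_fragment_mappings()]; defaults to `samples$bam`.
#' @param mapq_min Minimum mapping quality (default 30).
#' @param coverage_threshold Covered-fraction threshold defining the
#'   surviving mask (default 0.5).
#' @param ... Passed to [count_fragment_mappings()].
#' @return A `fragment_count_table`.
#' @export
build_count_table <- function(fragments, samples, alignments = NULL,
                              mapq_min = 30, coverage_threshold = 0.5, ...) {
  samples <- validate_samples(samples)
  if (is.null(alignments)) {
    stopifnot("bam" %in% names(samples))
    alignments <- as.list(samples$bam)
    names(alignments) <- samples$sample_id
  }
  stopifnot(all(samples$sample_id %in% names(alignments)))
  counts <- covered <- matrix(0, nrow(fragments), nrow(samples),
                              dimnames = list(fragments$frag_id,
                                              samples$sample_id))
  totals <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    one <- count_fragment_mappings(alignments[[samples$sample_id[i]]],
                                   fragments, mapq_min = mapq_min, ...)
    counts[, i] <- one$counts
    covered[, i] <- one$covered_fraction
    totals[i] <- one$total_hq_mappings
  }
  samples$total_hq_mappings <- totals
  fragment_count_table(fragments, samples, counts, covered,
                       coverage_threshold = coverage_threshold)
}

validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "sex") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  if (!all(samples$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  if (is.null(samples$population)) samples$population <- "pop1"
  samples
}

#' Construct a fragment count table
#'
#' Container for the per-fragment, per-sample raw mapping counts and
#' covered fractions, with the surviving mask (covered fraction at or
#' above the coverage threshold).
#'
#' @param fragments Fragment table ([predict_fragments()] output shape).
#' @param samples Sample sheet including `total_hq_mappings`.
#' @param counts,covered_fraction Numeric fragments x samples matrices.
#' @param coverage_threshold Fraction in `[0, 1]` (default 0.5).
#' @return An object of class `fragment_count_table`.
#' @export
fragment_count_table <- function(fragments, samples, counts,
                                 covered_fraction, coverage_threshold = 0.5) {
  samples <- validate_samples(samples)
  stopifnot(is.matrix(counts), is.matrix(covered_fraction),
            nrow(counts) == nrow(fragments),
            ncol(counts) == nrow(samples),
            all(dim(counts) == dim(covered_fraction)),
            all(is.finite(counts)), all(counts >= 0),
            all(covered_fraction >= 0 & covered_fraction <= 1),
            coverage_threshold >= 0, coverage_threshold <= 1)
  if (!"total_hq_mappings" %in% names(samples))
    stop("samples must carry total_hq_mappings", call. = FALSE)
  if (any(colSums(counts) > samples$total_hq_mappings + 1e-8)) {
    # a mapping can overlap two adjacent fragments, so only flag gross
    # inconsistency: more fragment hits than total mappings times 2
    if (any(colSums(counts) > 2 * samples$total_hq_mappings))
      stop("fragment counts exceed total mappings for some sample",
           call. = FALSE)
  }
  dimnames(counts) <- dimnames(covered_fraction) <-
    list(fragments$frag_id, samples$sample_id)
  structure(
    list(fragments = fragments, samples = samples, counts = counts,
         covered_fraction = covered_fraction,
         coverage_threshold = coverage_threshold,
         surviving = covered_fraction >= coverage_threshold),
    class = "fragment_count_table"
  )
}

#' @export
print.fragment_count_table <- function(x, ...) {
  cat(sprintf("<fragment_count_table> %d fragments x %d samples (%d M / %d F)\n",
              nrow(x$counts), ncol(x$counts), sum(x$samples$sex == "M"),
              sum(x$samples$sex == "F")))
  invisible(x)
}

#' Default minimum-sample retention threshold
#'
#' The retention rule keeps a fragment only if enough samples survive its
#' coverage filter; the design threshold is 90% of the smallest sex
#' group, rounded down.
#'
#' @param samples Sample sheet with a `sex` column.
#' @param fraction Fraction of the smallest sex group (default 0.9).
#' @return Integer threshold.
#' @export
min_samples_default <- function(samples, fraction = 0.9) {
  as.integer(floor(fraction * min(table(factor(samples$sex,
                                               c("M", "F"))))))
}

#' Apply coverage and sample-retention filters
#'
#' Marks sample-fragment pairs whose covered fraction is below the
#' coverage threshold as non-surviving, then drops fragments for which
#' fewer than `min_samples` samples (both sexes pooled) survive. The
#' pooled count is essential: a male-specific fragment has zero surviving
#' females yet must be retained and tested.
#'
#' @param table A `fragment_count_table`.
#' @param coverage_threshold Covered-fraction threshold (default 0.5).
#' @param min_samples Minimum surviving samples per fragment (default 50).
#' @return A filtered `fragment_count_table` whose `report` component
#'   lists `n_pairs_masked` (pairs newly failing the coverage rule),
#'   `n_fragments_dropped` and `n_fragments_kept`.
#' @export
apply_filters <- function(table, coverage_threshold = 0.5, min_samples = 50) {
  stopifnot(inherits(table, "fragment_count_table"))
  if (min_samples > nrow(table$samples))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         nrow(table$samples), ")", call. = FALSE)
  surviving <- table$covered_fraction >= coverage_threshold
  n_surv <- rowSums(surviving)
  keep <- n_surv >= min_samples
  out <- fragment_count_table(
    table$fragments[keep, , drop = FALSE], table$samples,
    table$counts[keep, , drop = FALSE],
    table$covered_fraction[keep, , drop = FALSE],
    coverage_threshold = coverage_threshold
  )
  out$report <- list(
    n_pairs_masked = sum(!surviving),
    n_fragments_dropped = sum(!keep),
    n_fragments_kept = sum(keep),
    coverage_threshold = coverage_threshold,
    min_samples = min_samples
  )
  out
}

#' Normalize counts by per-sample library size
#'
#' Scales each sample's fragment counts by its total number of
#' high-quality mappings, times one million (counts per million HQ
#' mappings).
#'
#' @param table A `fragment_count_table`.
#' @return A `normalized_count_table` with a `values` matrix on the
#'   per-million scale; all other components are carried over.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "fragment_count_table"))
  lib <- table$samples$total_hq_mappings
  if (any(lib <= 0)) {
    bad <- table$samples$sample_id[lib <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  values <- sweep(table$counts, 2L, lib, "/") * 1e6
  out <- unclass(table)
  out$values <- values
  class(out) <- c("normalized_count_table", "fragment_count_table")
  out
}

#' Write the count-table matrices as TSV files
#'
#' Writes raw counts, covered fractions, and (if present) normalized
#' values as fragments-by-samples TSVs, plus the sample sheet.
#'
#' @param table A `fragment_count_table` or `normalized_count_table`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_count_tables <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(raw = file.path(dir, "raw_counts.tsv"),
             covered = file.path(dir, "covered_fraction.tsv"),
             samples = file.path(dir, "samples.tsv"),
             fragments = file.path(dir, "fragments.tsv"))
  write_matrix_tsv(table$counts, files["raw"])
  write_matrix_tsv(table$covered_fraction, files["covered"])
  write.table(table$samples, files["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(table$fragments, files["fragments"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(table$values)) {
    files["normalized"] <- file.path(dir, "normalized_counts.tsv")
    write_matrix_tsv(table$values, files["normalized"])
  }
  invisible(files)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(frag_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count-table directory written by [write_count_tables()]
#'
#' @param dir Directory holding `raw_counts.tsv`, `covered_fraction.tsv`,
#'   `samples.tsv` and `fragments.tsv`.
#' @param coverage_threshold Covered-fraction threshold for the surviving
#'   mask (default 0.5).
#' @return A `fragment_count_table`.
#' @export
read_count_tables <- function(dir, coverage_threshold = 0.5) {
  read_m <- function(f) {
    df <- read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  fragment_count_table(
    read.delim(file.path(dir, "fragments.tsv"), stringsAsFactors = FALSE),
    read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE),
    read_m("raw_counts.tsv"), read_m("covered_fraction.tsv"),
    coverage_threshold = coverage_threshold
  )
}
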