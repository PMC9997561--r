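#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition motif (IUPAC
#' nucleotide codes) and the offset, in bases from the 5' start of the
#' motif, at which the top strand is cut.
#'
#' @param name Short enzyme name, e.g. `"NsiI"`.
#' @param recognition Recognition motif as an IUPAC nucleotide string of
#'   length >= 4.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: bases from the 5'
#'   start of the motif to the top-strand cut position.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("NsiI", "ATGCAT", 5)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  if (nchar(recognition) < 4L)
    stop("recognition motif must be at least 4 bases long", call. = FALSE)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(recognition, "")[[1]]
  if (!all(chars %in% iupac))
    stop("invalid enzyme: recognition motif '", recognition,
         "' contains non-IUPAC characters", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within [0, motif length]", call. = FALSE)
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut at +%d)\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' Built-in ddRAD enzymes
#'
#' Look up one of the built-in enzymes used for the ddRAD design this
#' package targets: NsiI (ATGCAT, cutting after position 5, leaving a
#' 3' overhang) and MspI (CCGG, cutting after position 1). Both motifs
#' are palindromic, so a top-strand scan finds all double-strand sites.
#'
#' @param name `"NsiI"` or `"MspI"` (case-sensitive).
#' @return A `restriction_enzyme`.
#' @export
ddrad_enzyme <- function(name) {
  builtins <- list(
    NsiI = restriction_enzyme("NsiI", "ATGCAT", 5L),
    MspI = restriction_enzyme("MspI", "CCGG", 1L)
  )
  if (!name %in% names(builtins))
    stop("unknown built-in enzyme '", name, "'; use restriction_enzyme() ",
         "to define others", call. = FALSE)
  builtins[[name]]
}

#' Find restriction sites on the top strand
#'
#' Scans a nucleotide sequence for all (possibly overlapping) occurrences
#' of the enzyme's recognition motif, with IUPAC ambiguity codes in the
#' motif expanded. `N` in the subject sequence never matches. For the
#' palindromic built-in enzymes a top-strand scan is equivalent to
#' scanning both strands.
#'
#' @param sequence A nucleotide string (character or
#'   [Biostrings::DNAString]) over A/C/G/T/N, case-insensitive.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 0-based site start positions.
#' @export
find_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  if (length(sequence) < nchar(enzyme$recognition)) return(integer(0))
  # fixed = "subject": motif ambiguities are expanded, subject letters are
  # literal, so N in the genome never matches.
  m <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                sequence, fixed = "subject")
  sort(BiocGenerics::start(m) - 1L)
}

# Assemble fragments between consecutive cut positions on one chromosome.
# cuts: data.frame(pos = 0-based cut position, enzyme = name), possibly
# unsorted. Returns 0-based half-open intervals flanked by their enzymes.
fragments_from_cuts <- function(cuts, chrom) {
  if (nrow(cuts) < 2L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), left_enzyme = character(0),
                      right_enzyme = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  dup <- duplicated(cuts$pos)
  if (any(dup)) {
    warning("coincident cut positions from different enzymes on ", chrom,
            "; keeping the first", call. = FALSE)
    cuts <- cuts[!dup, , drop = FALSE]
  }
  n <- nrow(cuts)
  data.frame(
    chrom = chrom,
    start = cuts$pos[-n],
    end = cuts$pos[-1L],
    left_enzyme = cuts$enzyme[-n],
    right_enzyme = cuts$enzyme[-1L],
    length = cuts$pos[-1L] - cuts$pos[-n],
    stringsAsFactors = FALSE
  )
}

#' Predict ddRAD fragments by in-silico double digestion
#'
#' Digests each sequence with two restriction enzymes, pools the cut
#' positions (recognition start + cut offset), and emits the fragments
#' spanning consecutive cuts. Under the default `ends_rule =
#' "different_enzymes"` only fragments flanked by cuts from the two
#' different enzymes are kept -- the fragments a ddRAD library actually
#' sequences -- and size selection is applied to fragment length.
#'
#' Fragment boundaries are cut positions, not recognition-site edges, so
#' the intervals are the physical digestion products. Coordinates are
#' 0-based half-open. Chromosomes are processed in name order, so the
#' result does not depend on the input sequence order.
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome/scaffold sequences, or a path to a FASTA file (plain or
#'   gzip).
#' @param enzyme_a,enzyme_b [restriction_enzyme()] objects (defaults: NsiI
#'   and MspI).
#' @param min_len,max_len Size-selection bounds in bp (defaults 0 and 613,
#'   the maximum selected size of the targeted library design).
#' @param ends_rule `"different_enzymes"` (default, standard ddRAD) or
#'   `"any"` to also keep same-enzyme fragments.
#' @param boundaries `"cut"` (default; fragment boundaries at cut
#'   positions) or `"site_edge"` (boundaries at recognition-site starts),
#'   exposed because digestion-prediction tools differ on this convention.
#' @return A data.frame with columns `chrom`, `start`, `end`,
#'   `left_enzyme`, `right_enzyme`, `length`, `frag_id`; fragments on a
#'   chromosome are sorted and non-overlapping.
#' @export
predict_fragments <- function(genome,
                              enzyme_a = ddrad_enzyme("NsiI"),
                              enzyme_b = ddrad_enzyme("MspI"),
                              min_len = 0L, max_len = 613L,
                              ends_rule = c("different_enzymes", "any"),
                              boundaries = c("cut", "site_edge")) {
  ends_rule <- match.arg(ends_rule)
  boundaries <- match.arg(boundaries)
  stopifnot(min_len >= 0L, min_len <= max_len)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (length(genome) == 0L) stop("genome is empty", call. = FALSE)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named", call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))

  same <- identical(enzyme_a$recognition, enzyme_b$recognition)
  if (same && ends_rule == "different_enzymes") {
    warning("both enzymes have the same recognition motif; no fragment can ",
            "have different-enzyme ends", call. = FALSE)
    return(cbind(fragments_from_cuts(data.frame(pos = integer(0),
                                                enzyme = character(0)), ""),
                 frag_id = character(0))[0, ])
  }

  off_a <- if (boundaries == "cut") enzyme_a$cut_offset else 0L
  off_b <- if (boundaries == "cut") enzyme_b$cut_offset else 0L

  out <- lapply(sort(names(genome)), function(chrom) {
    seq <- genome[[chrom]]
    pos_a <- find_sites(seq, enzyme_a) + off_a
    pos_b <- find_sites(seq, enzyme_b) + off_b
    cuts <- data.frame(
      pos = c(pos_a, pos_b),
      enzyme = c(rep(enzyme_a$name, length(pos_a)),
                 rep(enzyme_b$name, length(pos_b))),
      stringsAsFactors = FALSE
    )
    fragments_from_cuts(cuts, chrom)
  })
  frags <- do.call(rbind, out)
  if (ends_rule == "different_enzymes")
    frags <- frags[frags$left_enzyme != frags$right_enzyme, , drop = FALSE]
  frags <- frags[frags$length >= min_len & frags$length <= max_len, ,
                 drop = FALSE]
  rownames(frags) <- NULL
  frags$frag_id <- sprintf("%s-%s_%05d", frags$left_enzyme,
                           frags$right_enzyme, seq_len(nrow(frags)))
  frags
}

#' Write predicted fragments as BED6
#'
#' @param fragments Fragment table from [predict_fragments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    fragments$frag_id, fragments$length, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment BED6 file written by [write_fragments_bed()]
#'
#' @param path BED file path.
#' @return A fragment data.frame as from [predict_fragments()].
#' @export
read_fragments_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  enz <- strsplit(sub("_[0-9]+$", "", bed[[4]]), "-")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             left_enzyme = vapply(enz, `[`, "", 1L),
             right_enzyme = vapply(enz, `[`, "", 2L),
             length = bed[[3]] - bed[[2]], frag_id = bed[[4]],
             stringsAsFactors = FALSE)
}
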