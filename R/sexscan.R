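#' Two-sample Monte Carlo (permutation) test on one fragment
#'
#' Tests whether a fragment's normalized counts differ between males and
#' females by shuffling the sex labels. The statistic is the absolute
#' difference of group means (two-sided). Labels are permuted uniformly
#' `n_reps` times; ties with the observed statistic count as
#' exceedances. Two p-value estimators are available: `add_one`,
#' `(b + 1) / (n_reps + 1)`, which can never return zero and is the safe
#' default, and `plug_in`, `b / n_reps`, which can return an exact zero
#' and is required for any test to clear stringent multiple-testing
#' thresholds when the number of tests is large relative to `n_reps`
#' (see [bh_feasibility()]).
#'
#' @param values Numeric vector of per-sample normalized counts.
#' @param labels Character/factor vector of `"M"`/`"F"` per sample.
#' @param n_reps Number of label permutations (default 100000).
#' @param statistic Only `"abs_mean_diff"` is implemented.
#' @param seed Integer RNG seed; results are reproducible given the seed.
#' @param estimator `"add_one"` (default) or `"plug_in"`.
#' @return List with `stat_obs`, `p_value`, `n_exceed`, `n_reps`,
#'   `estimator`.
#' @export
permutation_test <- function(values, labels, n_reps = 100000L,
                             statistic = "abs_mean_diff", seed = 1L,
                             estimator = c("add_one", "plug_in")) {
  estimator <- match.arg(estimator)
  statistic <- match.arg(statistic, "abs_mean_diff")
  stopifnot(length(values) == length(labels), n_reps >= 1L)
  labels <- as.character(labels)
  if (!all(labels %in% c("M", "F")))
    stop("labels must be 'M' or 'F'", call. = FALSE)
  is_m <- labels == "M"
  if (!any(is_m) || all(is_m))
    stop("both label classes must be non-empty; fragment should have been ",
         "dropped upstream", call. = FALSE)
  stat_obs <- abs(mean(values[is_m]) - mean(values[!is_m]))
  old <- get0(".Random.seed", globalenv())
  set.seed(as.integer(seed) %% 2147483647L)
  b <- perm_exceed_count(as.numeric(values), is_m, as.integer(n_reps))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- switch(estimator,
              add_one = (b + 1) / (n_reps + 1),
              plug_in = b / n_reps)
  list(stat_obs = stat_obs, p_value = p, n_exceed = b,
       n_reps = as.integer(n_reps), estimator = estimator)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `q_i = min_{j >= i} (p_j * m / j)` clipped at 1, returned
#' in the input order (a thin validating wrapper around
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Classify a fragment's male/female coverage pattern
#'
#' Labels the direction and shape of a coverage difference:
#' `male_specific` when no female sample survives the coverage filter but
#' males map (the signature of a male-only, Y-linked region);
#' `female_specific` symmetrically; `female_elevated` when both sexes map
#' but the female mean is about twice the male mean (the signature of a
#' duplicated/X-linked region), i.e. within `(2 - 2 * ratio_tol, 2 +
#' 2 * ratio_tol)` times the male mean; `male_elevated` symmetrically;
#' `other` otherwise.
#'
#' @param male_mean,female_mean Group means of normalized counts.
#' @param n_male_surviving,n_female_surviving Surviving sample counts.
#' @param ratio_tol Relative tolerance on the doubling ratio
#'   (default 0.25, accepting ratios in `[1.5, 2.5]`).
#' @return One of `"male_specific"`, `"female_specific"`,
#'   `"female_elevated"`, `"male_elevated"`, `"other"`.
#' @export
classify_pattern <- function(male_mean, female_mean, n_male_surviving,
                             n_female_surviving, ratio_tol = 0.25) {
  lo <- 2 - 2 * ratio_tol
  hi <- 2 + 2 * ratio_tol
  if (n_female_surviving == 0L && male_mean > 0) return("male_specific")
  if (n_male_surviving == 0L && female_mean > 0) return("female_specific")
  if (male_mean > 0 && female_mean > 0) {
    r_f <- female_mean / male_mean
    if (r_f >= lo && r_f <= hi) return("female_elevated")
    r_m <- male_mean / female_mean
    if (r_m >= lo && r_m <= hi) return("male_elevated")
  }
  "other"
}

#' Merge contiguous significant fragments into candidate sex regions
#'
#' Fragments whose adjusted p-value clears `alpha` and that are
#' consecutive in their chromosome's fragment ordering are merged into a
#' single region spanning from the first member's start to the last
#' member's end; the region's pattern is the majority pattern of its
#' members.
#'
#' @param results Per-fragment results data.frame from [sex_scan()]
#'   (needs `chrom`, `start`, `end`, `frag_id`, `p_adjusted`, `pattern`).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param strict Use `p_adjusted < alpha` (default); `FALSE` uses `<=`.
#' @return Data.frame of regions: `chrom`, `start`, `end`,
#'   `n_fragments`, `pattern`, `frag_ids` (comma-separated).
#' @export
merge_significant_regions <- function(results, alpha = 0.05, strict = TRUE) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_fragments = integer(0),
                      pattern = character(0), frag_ids = character(0),
                      stringsAsFactors = FALSE)
  sig <- if (strict) results$p_adjusted < alpha else results$p_adjusted <= alpha
  sig[is.na(sig)] <- FALSE
  if (!any(sig)) return(empty)
  regions <- lapply(unique(results$chrom), function(chrom) {
    r <- results[results$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    idx <- which(if (strict) r$p_adjusted < alpha else r$p_adjusted <= alpha)
    if (length(idx) == 0L) return(empty)
    run <- cumsum(c(1L, diff(idx) != 1L))
    do.call(rbind, lapply(split(idx, run), function(members) {
      pat <- r$pattern[members]
      data.frame(
        chrom = chrom,
        start = min(r$start[members]),
        end = max(r$end[members]),
        n_fragments = length(members),
        pattern = names(sort(table(pat), decreasing = TRUE))[1L],
        frag_ids = paste(r$frag_id[members], collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Feasibility of BH significance under a Monte Carlo p-value floor
#'
#' A Monte Carlo p-value with the `add_one` estimator can never fall
#' below `1 / (n_reps + 1)`. With `m` tests under Benjamini-Hochberg at
#' level `alpha`, a test at rank `k` can only be declared significant if
#' `p_floor <= alpha * k' / m` for some rank `k' >= k` that is itself
#' reached, so at least `ceiling(p_floor * m / alpha)` tests must sit at
#' the floor before any of them can pass. This function reports the
#' floor, the minimum attainable adjusted p-value when exactly `rank`
#' tests attain the floor (`p_floor * m / rank`), and the minimum number
#' of floor-level tests needed for significance. Under `plug_in` the
#' floor is zero and no such constraint exists.
#'
#' @param n_reps Permutation replicates per test.
#' @param m Number of tests entering the adjustment.
#' @param rank Rank of interest (default 25).
#' @param alpha BH level (default 0.05).
#' @param estimator `"add_one"` or `"plug_in"`.
#' @return List with `p_floor`, `min_adjusted_p_at_rank`,
#'   `min_tests_needed`, `feasible_at_rank`.
#' @export
bh_feasibility <- function(n_reps, m, rank = 25L, alpha = 0.05,
                           estimator = c("add_one", "plug_in")) {
  estimator <- match.arg(estimator)
  p_floor <- if (estimator == "add_one") 1 / (n_reps + 1) else 0
  min_adj <- min(p_floor * m / rank, 1)
  list(
    p_floor = p_floor,
    min_adjusted_p_at_rank = min_adj,
    min_tests_needed = if (p_floor == 0) 0L
                       else as.integer(ceiling(p_floor * m / alpha)),
    feasible_at_rank = min_adj < alpha
  )
}

#' Scan all fragments for sex-associated coverage differences
#'
#' Runs the per-fragment permutation test over a normalized count table,
#' adjusts p-values with Benjamini-Hochberg, classifies each fragment's
#' coverage pattern, and merges contiguous significant fragments into
#' candidate sex regions.
#'
#' Sample-fragment pairs that failed the coverage filter enter the test
#' as zero counts by default (`drop_masked = FALSE`): a male-specific
#' fragment has no surviving females, and excluding those samples would
#' make the comparison impossible. With `drop_masked = TRUE` only
#' surviving samples are permuted; fragments where one sex then has no
#' samples get `NA` p-values.
#'
#' Per-fragment RNG streams are derived deterministically from
#' `(seed, fragment index)`, so results do not depend on evaluation
#' order.
#'
#' @param table A `normalized_count_table` from [normalize_counts()].
#' @param n_reps Permutation replicates per fragment (default 100000).
#' @param alpha BH significance level (default 0.05).
#' @param estimator P-value estimator, see [permutation_test()].
#' @param seed Master RNG seed.
#' @param ratio_tol Doubling-ratio tolerance for [classify_pattern()].
#' @param drop_masked Permute surviving samples only (default FALSE).
#' @param strict Strict inequality at `alpha` (default TRUE).
#' @return List of class `sex_scan` with `results` (per-fragment
#'   data.frame), `regions` (from [merge_significant_regions()]),
#'   `feasibility` (from [bh_feasibility()]) and `params`.
#' @export
sex_scan <- function(table, n_reps = 100000L, alpha = 0.05,
                     estimator = c("add_one", "plug_in"), seed = 1L,
                     ratio_tol = 0.25, drop_masked = FALSE, strict = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(table, "normalized_count_table"))
  m <- nrow(table$values)
  labels <- table$samples$sex
  is_m <- labels == "M"
  res <- vector("list", m)
  for (i in seq_len(m)) {
    surv <- table$surviving[i, ]
    vals <- table$values[i, ]
    if (drop_masked) {
      use <- surv
    } else {
      vals[!surv] <- 0
      use <- rep(TRUE, length(vals))
    }
    male_mean <- if (any(use & is_m)) mean(vals[use & is_m]) else 0
    female_mean <- if (any(use & !is_m)) mean(vals[use & !is_m]) else 0
    testable <- any(use & is_m) && any(use & !is_m)
    if (testable) {
      pt <- permutation_test(vals[use], labels[use], n_reps = n_reps,
                             seed = derive_seed(seed, i),
                             estimator = estimator)
      stat_obs <- pt$stat_obs; p <- pt$p_value
    } else {
      stat_obs <- NA_real_; p <- NA_real_
    }
    res[[i]] <- data.frame(
      frag_id = table$fragments$frag_id[i],
      chrom = table$fragments$chrom[i],
      start = table$fragments$start[i],
      end = table$fragments$end[i],
      stat_obs = stat_obs, p_value = p,
      male_mean = male_mean, female_mean = female_mean,
      n_male_surviving = sum(surv & is_m),
      n_female_surviving = sum(surv & !is_m),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res)
  results$p_adjusted <- NA_real_
  ok <- !is.na(results$p_value)
  results$p_adjusted[ok] <- bh_adjust(results$p_value[ok])
  results$pattern <- mapply(classify_pattern, results$male_mean,
                            results$female_mean, results$n_male_surviving,
                            results$n_female_surviving,
                            MoreArgs = list(ratio_tol = ratio_tol))
  regions <- merge_significant_regions(results, alpha = alpha,
                                       strict = strict)
  structure(
    list(results = results, regions = regions,
         feasibility = bh_feasibility(n_reps, sum(ok), alpha = alpha,
                                      estimator = estimator),
         params = list(n_reps = as.integer(n_reps), alpha = alpha,
                       estimator = estimator, seed = as.integer(seed),
                       ratio_tol = ratio_tol, drop_masked = drop_masked,
                       strict = strict)),
    class = "sex_scan"
  )
}

#' @export
print.sex_scan <- function(x, ...) {
  sig <- sum(x$results$p_adjusted < x$params$alpha, na.rm = TRUE)
  cat(sprintf(paste0(
    "<sex_scan> %d fragments tested, %d significant (BH %s %.3g), ",
    "%d region(s)\n  n_reps=%d estimator=%s seed=%d\n"),
    sum(!is.na(x$results$p_value)), sig,
    if (x$params$strict) "<" else "<=", x$params$alpha,
    nrow(x$regions), x$params$n_reps, x$params$estimator, x$params$seed))
  if (!x$feasibility$feasible_at_rank && x$params$estimator == "add_one")
    cat(sprintf(paste0(
      "  note: add_one p-value floor %.3g makes BH %.3g unreachable at ",
      "rank 25 unless >= %d tests sit at the floor\n"),
      x$feasibility$p_floor, x$params$alpha,
      x$feasibility$min_tests_needed))
  invisible(x)
}

#' Write sex-scan outputs
#'
#' Writes the per-fragment results TSV, the regions BED (pattern in the
#' name field) and a log of the run parameters.
#'
#' @param scan A `sex_scan` object.
#' @param dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
write_sex_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(results = file.path(dir, "sexscan_results.tsv"),
             regions = file.path(dir, "sex_regions.bed"),
             log = file.path(dir, "sexscan_log.txt"))
  write.table(scan$results, files["results"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  reg <- scan$regions
  if (nrow(reg) > 0L) {
    bed <- data.frame(reg$chrom, reg$start, reg$end,
                      paste0(reg$pattern, "_", seq_len(nrow(reg))),
                      reg$n_fragments, rep(".", nrow(reg)))
    write.table(bed, files["regions"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(files["regions"])
  }
  writeLines(c(
    sprintf("n_reps\t%d", scan$params$n_reps),
    sprintf("alpha\t%g", scan$params$alpha),
    sprintf("estimator\t%s", scan$params$estimator),
    sprintf("seed\t%d", scan$params$seed),
    sprintf("min_adjusted_p_at_rank25\t%g",
            scan$feasibility$min_adjusted_p_at_rank)
  ), files["log"])
  invisible(files)
}
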