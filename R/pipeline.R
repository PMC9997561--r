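#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with the
#' design defaults: mapq 30, covered-fraction threshold 0.5, minimum 50
#' surviving samples, 613 bp maximum fragment size, 100,000 permutation
#' replicates, BH level 0.05, 10 kb windows, 0.9 site-presence
#' threshold. Any element supplied in `...` (or nested via a list)
#' overrides the default.
#'
#' @param ... Named overrides, e.g. `seed = 7`,
#'   `scan = list(n_reps = 2000)`.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(n_chrom = 2L, chrom_len = 50000L,
                  site_rate_per_kb = c(NsiI = 0.4, MspI = 2)),
    digest = list(min_len = 0L, max_len = 613L,
                  ends_rule = "different_enzymes"),
    counts = list(n_fragments = 500L, n_male = 64L, n_female = 56L,
                  mean_depth = 20, coverage_threshold = 0.5,
                  min_samples = 50L,
                  planted_male_specific = 1:5,
                  planted_female_doubled = 11:15),
    scan = list(n_reps = 2000L, alpha = 0.05, estimator = "add_one",
                ratio_tol = 0.25),
    popgen = list(n_sites = 2000L, target_fst = 0.1, missing_rate = 0.05,
                  window_size = 10000L, min_presence = 0.9)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("configuration error: ", msg,
                                         call. = FALSE)
  chk(cfg$counts$coverage_threshold >= 0 && cfg$counts$coverage_threshold <= 1,
      "coverage_threshold must lie in [0, 1]")
  chk(cfg$scan$alpha > 0 && cfg$scan$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$scan$n_reps >= 1, "n_reps must be positive")
  chk(cfg$digest$min_len >= 0 && cfg$digest$min_len <= cfg$digest$max_len,
      "size selection bounds must satisfy 0 <= min_len <= max_len")
  chk(cfg$popgen$window_size >= 1, "window_size must be positive")
  chk(cfg$popgen$min_presence >= 0 && cfg$popgen$min_presence <= 1,
      "min_presence must lie in [0, 1]")
  chk(cfg$counts$min_samples <= cfg$counts$n_male + cfg$counts$n_female,
      "min_samples exceeds the number of samples")
  invisible(cfg)
}

#' Run the full synthetic-data pipeline
#'
#' Orchestrates all stages on simulated inputs: genome simulation and
#' in-silico digestion; count-table simulation, filtering, normalization
#' and the sex scan; genotype simulation, site-presence filtering and
#' windowed population statistics. Every stage's outputs are written
#' under `out_dir` and recorded, with their MD5 hashes and all parameter
#' values, in a machine-readable manifest; rerunning with an identical
#' configuration reproduces identical files.
#'
#' @param config Configuration list from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `status` (0 on success), `manifest` (path) and
#'   `outputs` (named file paths), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  outputs <- character(0)

  # stage 1: genome + digestion
  gen <- simulate_genome(
    n_chrom = config$genome$n_chrom, chrom_len = config$genome$chrom_len,
    site_rate_per_kb = config$genome$site_rate_per_kb,
    min_len = config$digest$min_len, max_len = config$digest$max_len,
    ends_rule = config$digest$ends_rule, seed = seed
  )
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(gen$sequences, fa)
  frags <- predict_fragments(gen$sequences,
                             min_len = config$digest$min_len,
                             max_len = config$digest$max_len,
                             ends_rule = config$digest$ends_rule)
  bed <- file.path(out_dir, "fragments.bed")
  write_fragments_bed(frags, bed)
  tsv <- file.path(out_dir, "fragments.tsv")
  write.table(frags, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, genome = fa, fragments_bed = bed,
               fragments_tsv = tsv)

  # stage 2: counts + filters + normalization
  sim <- simulate_count_table(
    n_fragments = config$counts$n_fragments,
    n_male = config$counts$n_male, n_female = config$counts$n_female,
    mean_depth = config$counts$mean_depth,
    planted_male_specific = config$counts$planted_male_specific,
    planted_female_doubled = config$counts$planted_female_doubled,
    seed = derive_seed(seed, 101L)
  )
  filtered <- apply_filters(sim$table,
                            coverage_threshold =
                              config$counts$coverage_threshold,
                            min_samples = config$counts$min_samples)
  norm <- normalize_counts(filtered)
  cfiles <- write_count_tables(norm, file.path(out_dir, "counts"))
  outputs <- c(outputs, cfiles)

  # stage 3: sex scan
  scan <- sex_scan(norm, n_reps = config$scan$n_reps,
                   alpha = config$scan$alpha,
                   estimator = config$scan$estimator,
                   seed = derive_seed(seed, 202L),
                   ratio_tol = config$scan$ratio_tol)
  sfiles <- write_sex_scan(scan, file.path(out_dir, "sexscan"))
  outputs <- c(outputs, sfiles)

  # stage 4: popgen windows
  simg <- simulate_genotypes(n_sites = config$popgen$n_sites,
                             target_fst = config$popgen$target_fst,
                             missing_rate = config$popgen$missing_rate,
                             seed = derive_seed(seed, 303L))
  gm <- filter_sites_by_presence(simg$gm, config$popgen$min_presence)
  win <- popgen_windows(gm, window_size = config$popgen$window_size)
  pfile <- file.path(out_dir, "popgen_windows.tsv")
  write.table(win, pfile, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, popgen = pfile)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    seed = seed,
    config = config,
    outputs = lapply(as.list(outputs), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(status = 0L, manifest = manifest_path, outputs = outputs))
}
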