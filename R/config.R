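#' Default run configuration
#'
#' Returns every tunable default of the simulation in one named list.
#' The defaults are the full-scale study conditions (3,000 accessions,
#' a 100,000-candidate-marker genome, 1,000 QTL); `scale` shrinks
#' population sizes proportionally for desk runs while leaving the
#' factor levels of [scenario_grid()] untouched.
#'
#' @param scale population-scale factor in `(0, 1]`.
#' @return named list of class `prebreed_config`.
#' @export
default_config <- function(scale = 1) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  structure(list(
    scale = scale,
    # genome
    n_chrom = 10L,
    chrom_length_morgan = 2,
    candidate_loci_per_chrom = max(50L, as.integer(round(10000 * scale))),
    n_qtl = max(10L, as.integer(round(1000 * scale))),
    mutation_rate = 1e-6,
    maf_min = 0.05,
    # founders and landraces
    n_founder_haplotypes = max(40L, as.integer(round(4000 * scale))),
    n_accessions = max(20L, as.integer(round(3000 * scale))),
    pool_size = 20L,
    founders_per_accession = 4L,
    landrace_generations = 10L,
    landrace_ref_per_accession = 2L,
    # elite construction
    elite_selection_generations = 5L,
    elite_subpop_size = 50L,
    elite_top_frac = 0.1,
    # genotyping; marker panels scale separately from population sizes
    # so desk runs can trade panel density against runtime
    gbs_error_rate = 0.005,
    marker_scale = scale,
    # program logistics
    n_units = 10L,
    dh_candidates = 10L,
    seeds_per_cycle_plant = 10L,
    improvement_cycles = 4L,
    # metrics
    segment_cm = 1,
    kinship_mode = "ibd",
    het_sites_cap = 5000L,
    seasons_map = list(Landrace = 6, LandraceDH = 9, LandraceElite = 6)
  ), class = "prebreed_config")
}

#' Validate a configuration list
#'
#' Unknown keys are rejected; closed vocabularies (kinship mode) are
#' enforced; sizes and rates must be positive where required.
#'
#' @param config a configuration list.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  with(config, {
    stopifnot(scale > 0, scale <= 1, n_chrom >= 1, chrom_length_morgan > 0,
              candidate_loci_per_chrom >= 1, n_qtl >= 1, mutation_rate > 0,
              maf_min >= 0, maf_min < 0.5, n_founder_haplotypes >= 4,
              n_accessions >= 1, pool_size >= 2, founders_per_accession >= 2,
              landrace_generations >= 1, landrace_generations <= 20,
              gbs_error_rate >= 0, gbs_error_rate < 0.5,
              marker_scale > 0, marker_scale <= 1, n_units >= 2,
              dh_candidates >= 1, seeds_per_cycle_plant >= 1,
              improvement_cycles >= 1, segment_cm > 0)
  })
  if (!config$kinship_mode %in% c("ibd", "ibs")) {
    stop("kinship_mode must be 'ibd' or 'ibs'")
  }
  invisible(config)
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take their defaults; unknown keys are an error. An
#' empty file yields the full default configuration. Factor levels
#' outside the study grid (e.g. `Ne: 5`) are allowed in scenario
#' subsets when `strict = FALSE` is used downstream.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `config` (a validated
#'   [default_config()]-shaped list), `run` (master_seed,
#'   n_replicates, out, factors) and `hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  run_keys <- c("master_seed", "n_replicates", "out", "factors", "scale")
  run <- raw[intersect(names(raw), run_keys)]
  cfg_in <- raw[setdiff(names(raw), setdiff(run_keys, "scale"))]
  cfg <- utils::modifyList(default_config(scale = run$scale %||% 1), cfg_in,
                           keep.null = FALSE)
  validate_config(cfg)
  if (!is.null(run$factors)) validate_factor_subset(run$factors)
  list(config = cfg, run = run, hash = config_hash(cfg))
}

validate_factor_subset <- function(factors) {
  known <- c("approach", "Ne", "F_within", "h2", "platform",
             "seeds_per_landrace", "n_selected_landraces",
             "tested_seeds_per_landrace", "n_synthetic_phenotypes")
  unknown <- setdiff(names(factors), known)
  if (length(unknown)) {
    stop("unknown design factors: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(factors$approach) &&
      !all(factors$approach %in% c("Landrace", "LandraceDH", "LandraceElite"))) {
    stop("approach must be one of Landrace, LandraceDH, LandraceElite")
  }
  if (!is.null(factors$platform) &&
      !all(factors$platform %in% c("GBS10x@10K", "GBS1x@100K"))) {
    stop("platform must be one of GBS10x@10K, GBS1x@100K")
  }
  invisible(factors)
}

#' Stable hash of a configuration
#'
#' @param config a configuration list.
#' @return a short hash string recorded in run provenance.
#' @export
config_hash <- function(config) {
  rlang::hash(config[order(names(config))])
}

#' Write and read stage-record tables
#'
#' Records go to a tidy CSV with a stable column order; provenance
#' (config hash, master seed, scale) goes to a JSON sidecar
#' `<path>.meta.json`. Appending resumes a partial grid without
#' duplicating a (scenario, replicate, stage) key. Missing metrics
#' round-trip as empty fields.
#'
#' @param records a stage-record tibble from [run_grid()].
#' @param path output CSV path.
#' @param append resume an existing file, dropping duplicate keys.
#' @param provenance optional list written to the sidecar; defaults to
#'   the records' provenance attribute.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, append = FALSE, provenance = NULL) {
  provenance <- provenance %||% attr(records, "provenance")
  cols <- c("scenario_id", "approach", "Ne", "F_within", "h2", "platform",
            "seeds_per_landrace", "n_selected_landraces",
            "tested_seeds_per_landrace", "n_synthetic_phenotypes",
            "replicate", "stage", "merit", "accuracy",
            "kinship_with_elite", "heterozygosity")
  records <- records[, cols]
  if (append && file.exists(path)) {
    old <- read_records(path)
    key <- function(d) paste(d$scenario_id, d$replicate, d$stage)
    records <- rbind(old, records[!key(records) %in% key(old), ])
  }
  write.csv(records, path, row.names = FALSE, na = "")
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(d)
}
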