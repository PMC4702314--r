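#' Define one scenario of the factorial design
#'
#' A scenario fixes the nine design factors: the initiation approach,
#' the founder diversity (Ne), the within-accession inbreeding (F), the
#' trait heritability, the GBS platform, the number of phenotyped seeds
#' per landrace, the number of selected landraces, the number of tested
#' seeds per selected landrace, and the number of phenotyped synthetic
#' seeds for retraining.
#'
#' @param approach one of `"Landrace"`, `"LandraceDH"`, `"LandraceElite"`.
#' @param Ne effective population size of the founding population.
#' @param F_within within-accession inbreeding coefficient.
#' @param h2 testcross heritability.
#' @param platform `"GBS10x@10K"` or `"GBS1x@100K"`.
#' @param seeds_per_landrace phenotyped seeds per landrace (1, 3, 5).
#' @param n_selected_landraces selected landraces (40, 80).
#' @param tested_seeds_per_landrace tested seeds per selected landrace
#'   (10, 20, 40).
#' @param n_synthetic_phenotypes phenotyped synthetic seeds per cycle
#'   (0, 20, 40, 60).
#' @param strict if `TRUE` (default), factor levels outside the study
#'   grid are rejected.
#' @return an object of class `scenario`.
#' @export
scenario <- function(approach, Ne, F_within, h2, platform,
                     seeds_per_landrace, n_selected_landraces,
                     tested_seeds_per_landrace, n_synthetic_phenotypes,
                     strict = TRUE) {
  approach <- match.arg(approach, c("Landrace", "LandraceDH", "LandraceElite"))
  platform <- match.arg(platform, c("GBS10x@10K", "GBS1x@100K"))
  if (strict) {
    chk <- function(x, levels, name) {
      if (!x %in% levels) {
        stop("factor ", name, " = ", x, " is outside the study grid (",
             paste(levels, collapse = ", "), ")")
      }
    }
    chk(Ne, c(1000, 100000), "Ne")
    chk(F_within, c(0.3, 0.9), "F")
    chk(h2, c(0.25, 0.5), "h2")
    chk(seeds_per_landrace, c(1, 3, 5), "seeds_per_landrace")
    chk(n_selected_landraces, c(40, 80), "n_selected_landraces")
    chk(tested_seeds_per_landrace, c(10, 20, 40), "tested_seeds_per_landrace")
    chk(n_synthetic_phenotypes, c(0, 20, 40, 60), "n_synthetic_phenotypes")
  }
  structure(list(
    approach = approach, Ne = Ne, F_within = F_within, h2 = h2,
    platform = platform, seeds_per_landrace = as.integer(seeds_per_landrace),
    n_selected_landraces = as.integer(n_selected_landraces),
    tested_seeds_per_landrace = as.integer(tested_seeds_per_landrace),
    n_synthetic_phenotypes = as.integer(n_synthetic_phenotypes)
  ), class = "scenario")
}

#' Enumerate the full factorial scenario grid
#'
#' The full design crosses 3 approaches x 2 Ne x 2 F x 2 h2 x
#' 2 platforms x 3 seeds-per-landrace x 2 selected-landrace counts x
#' 3 tested-seed counts x 4 synthetic-phenotype counts = 3,456
#' scenarios.
#'
#' @return a tibble with one row per scenario and a `scenario_id` key.
#' @export
scenario_grid <- function() {
  g <- expand.grid(
    n_synthetic_phenotypes = c(0L, 20L, 40L, 60L),
    tested_seeds_per_landrace = c(10L, 20L, 40L),
    n_selected_landraces = c(40L, 80L),
    seeds_per_landrace = c(1L, 3L, 5L),
    platform = c("GBS10x@10K", "GBS1x@100K"),
    h2 = c(0.25, 0.5),
    F_within = c(0.3, 0.9),
    Ne = c(1000, 100000),
    approach = c("Landrace", "LandraceDH", "LandraceElite"),
    stringsAsFactors = FALSE
  )
  g <- g[, c("approach", "Ne", "F_within", "h2", "platform",
             "seeds_per_landrace", "n_selected_landraces",
             "tested_seeds_per_landrace", "n_synthetic_phenotypes")]
  if (anyDuplicated(g)) stop("duplicate scenario ids in grid")
  tibble::as_tibble(cbind(scenario_id = seq_len(nrow(g)), g))
}

#' Build a simulated world shared by scenarios
#'
#' A world is everything upstream of the breeding-program logistics:
#' the genome map and founder panel at a given Ne, the landrace
#' accessions at a given F, the trait architecture, the elite package,
#' the frozen segregating-site set, and the merit scale. Scenarios that
#' differ only in logistical factors (and heritability, which enters at
#' phenotyping) share a world within a replicate.
#'
#' @param Ne effective population size.
#' @param F_within within-accession inbreeding target.
#' @param config a [default_config()] list (controls sizes and rates).
#' @param seed integer seed.
#' @return an object of class `sim_world`.
#' @export
build_world <- function(Ne, F_within, config = default_config(), seed = 1) {
  seeds <- derive_seeds(seed, 5)
  template <- genome_map_template(
    n_chrom = config$n_chrom,
    chrom_length_morgan = config$chrom_length_morgan,
    candidate_loci_per_chrom = config$candidate_loci_per_chrom,
    n_qtl = config$n_qtl
  )
  panel <- simulate_founders(template, Ne, config$n_founder_haplotypes,
                             seed = seeds[1],
                             mutation_rate = config$mutation_rate,
                             maf_min = config$maf_min)
  accessions <- found_landraces(panel, config$n_accessions, F_within,
                                pool_size = config$pool_size,
                                founders_per_accession = config$founders_per_accession,
                                generations = config$landrace_generations,
                                seed = seeds[2])
  trait <- sample_trait(panel$map, seed = seeds[3])

  # Landrace reference sample: merit scale, accession mean TBVs, and the
  # frozen segregating-site set all come from it.
  ref <- with_seed(seeds[4], {
    lapply(accessions, function(acc) {
      acc$pool[sample.int(length(acc$pool),
                          min(config$landrace_ref_per_accession,
                              length(acc$pool)))]
    })
  })
  ref_flat <- unlist(ref, recursive = FALSE)
  ref_tbv <- tbv(ref_flat, trait, panel)
  acc_sizes <- lengths(ref)
  acc_mean_tbv <- as.numeric(tapply(ref_tbv, rep(seq_along(ref), acc_sizes), mean))

  freq <- colMeans(dosage_at(ref_flat, seq_len(panel$map$n_loci), panel)) / 2
  seg_sites <- which(freq > 0 & freq < 1)
  if (length(seg_sites) > config$het_sites_cap) {
    seg_sites <- with_seed(seeds[4] + 1, sort(sample(seg_sites, config$het_sites_cap)))
  }

  elite <- breed_elite(panel, trait,
                       n_selection_generations = config$elite_selection_generations,
                       subpop_size = config$elite_subpop_size,
                       top_frac = config$elite_top_frac,
                       seed = seeds[5],
                       min_tbv = mean(ref_tbv))
  scale <- merit_scale(mean(ref_tbv), tbv(elite$elite_hybrid, trait, panel),
                       sd(ref_tbv))

  structure(list(
    map = panel$map, panel = panel, accessions = accessions,
    trait = trait, elite = elite, merit = scale,
    seg_sites = seg_sites, acc_mean_tbv = acc_mean_tbv,
    Ne = Ne, F_within = F_within, config = config, seed = seed
  ), class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world> Ne = ", x$Ne, ", F = ", x$F_within, ", ",
      length(x$accessions), " accessions, ", x$map$n_loci, " loci\n", sep = "")
  invisible(x)
}

stage_record <- function(stage, inds, acc_value, world, eq_ebv = NULL,
                         eq_tbv = NULL) {
  bv <- tbv(inds, world$trait, world$panel)
  tibble::tibble(
    stage = stage,
    merit = normalized_merit(bv, world$merit),
    accuracy = acc_value,
    kinship_with_elite = segment_kinship(inds, world$elite, world$panel,
                                         segment_cm = world$config$segment_cm,
                                         mode = world$config$kinship_mode),
    heterozygosity = heterozygosity(inds, world$seg_sites, world$panel)
  )
}

#' Run the discovery phase of one scenario
#'
#' Stage 1 grows `seeds_per_landrace` seeds per accession, testcrosses
#' each to the elite hybrid, phenotypes the testcrosses, and trains the
#' ridge equation on the landrace-seed genotypes. Stage 2 ranks
#' accessions by the mean EBV of their training seeds and keeps the
#' best. Stage 3 genotypes fresh random seeds from the selected
#' accessions and selects the best 10 by EBV with at most one seed per
#' accession; the initiation approach then decides the selected units
#' (the seeds, their best doubled haploids, or their testcrosses to the
#' elite hybrid).
#'
#' @param world a `sim_world`.
#' @param scn a [scenario()].
#' @param seed integer seed.
#' @return list with `units` (10 individuals), `eq`, `trait` (with
#'   calibrated `sigma_e`), `markers`, and `records` (stages T, A, S).
#' @export
run_discovery <- function(world, scn, seed = 1) {
  if (scn$n_selected_landraces > length(world$accessions)) {
    stop("scenario selects more landraces than the world contains")
  }
  cfg <- world$config
  map <- world$map
  panel <- world$panel
  hybrid <- world$elite$elite_hybrid
  with_seed(seed, {
    platform <- platform_preset(scn$platform,
                                scale = cfg$marker_scale %||% cfg$scale,
                                error_rate = cfg$gbs_error_rate)
    markers <- select_marker_panel(map, platform$n_markers)

    # Stage 1: training population and ridge equation.
    n_acc <- length(world$accessions)
    train_seeds <- vector("list", n_acc * scn$seeds_per_landrace)
    acc_of <- integer(length(train_seeds))
    k <- 0L
    for (a in seq_len(n_acc)) {
      s <- accession_seeds(world$accessions[[a]], scn$seeds_per_landrace,
                           map, world$F_within)
      for (x in s) {
        k <- k + 1L
        train_seeds[[k]] <- x
        acc_of[k] <- a
      }
    }
    tc <- lapply(train_seeds, function(s) cross(s, hybrid, map, role = "testcross"))
    tc_tbv <- tbv(tc, world$trait, world$panel)
    trait_cal <- calibrate_sigma_e(world$trait, tc_tbv, scn$h2)
    y <- tc_tbv + rnorm(length(tc_tbv), 0, trait_cal$sigma_e)

    geno_train <- gbs_genotype(train_seeds, platform, markers, panel)
    eq <- train_ridge(geno_train, y, scn$h2, training_id = "discovery")
    ebv_train <- predict_ebv(eq, geno_train)
    seed_tbv <- tbv(train_seeds, world$trait, panel)
    rec_t <- stage_record("T", train_seeds, accuracy(ebv_train, seed_tbv), world)

    # Stage 2: select accessions on mean EBV of their training seeds.
    acc_ebv <- as.numeric(tapply(ebv_train, acc_of, mean))
    sel_acc <- order(acc_ebv, decreasing = TRUE)[seq_len(scn$n_selected_landraces)]
    sel_pool <- unlist(lapply(world$accessions[sel_acc], `[[`, "pool"),
                       recursive = FALSE)
    rec_a <- stage_record("A", sel_pool,
                          accession_accuracy(acc_ebv, world$acc_mean_tbv),
                          world)

    # Stage 3: fresh seeds from the selected accessions.
    tested <- vector("list", scn$n_selected_landraces * scn$tested_seeds_per_landrace)
    tested_acc <- integer(length(tested))
    k <- 0L
    for (a in sel_acc) {
      s <- accession_seeds(world$accessions[[a]], scn$tested_seeds_per_landrace,
                           map, world$F_within)
      for (x in s) {
        k <- k + 1L
        x$id <- a  # accession of origin, carried into the selected units
        tested[[k]] <- x
        tested_acc[k] <- a
      }
    }
    geno_tested <- gbs_genotype(tested, platform, markers, panel)
    ebv_tested <- predict_ebv(eq, geno_tested)
    tested_tbv <- tbv(tested, world$trait, panel)
    acc_s <- accuracy(ebv_tested, tested_tbv)

    sel_seeds <- select_top_unique(ebv_tested, tested_acc, cfg$n_units)
    units <- switch(scn$approach,
      Landrace = tested[sel_seeds],
      LandraceDH = lapply(tested[sel_seeds], function(s) {
        dhs <- lapply(seq_len(cfg$dh_candidates), function(i) {
          make_dh(s, map)
        })
        dh_ebv <- predict_ebv(eq, gbs_genotype(dhs, platform, markers, panel))
        dhs[[which.max(dh_ebv)]]
      }),
      LandraceElite = lapply(tested[sel_seeds], function(s) {
        cross(s, hybrid, map, role = "landrace_elite")
      })
    )
    rec_s <- stage_record("S", units, acc_s, world)

    list(units = units, eq = eq, trait = trait_cal, markers = markers,
         platform = platform,
         records = rbind(rec_t, rec_a, rec_s))
  })
}

# Best n by score with at most one pick per group; ties broken by
# stable index order.
select_top_unique <- function(score, group, n) {
  o <- order(score, decreasing = TRUE)
  picked <- integer(0)
  seen <- integer(0)
  for (i in o) {
    if (!(group[i] %in% seen)) {
      picked <- c(picked, i)
      seen <- c(seen, group[i])
      if (length(picked) == n) break
    }
  }
  if (length(picked) < n) stop("fewer groups than requested selections")
  picked
}

#' Run the improvement phase of one scenario
#'
#' Four breeding cycles: the 10 current plants are mated at random, 10
#' seeds per plant are genotyped (100 altogether), EBVs use the
#' equation available in that cycle (the discovery equation in C1, the
#' previous cycle's retrained equation thereafter), and the best 10
#' seeds are selected. A random sample of the remaining seeds is
#' testcrossed to the elite hybrid for retraining; since two
#' generations are needed for testcross phenotypes, an updated equation
#' is usable only in the next cycle. With zero phenotyped synthetic
#' seeds the discovery equation persists throughout.
#'
#' @param world a `sim_world`.
#' @param scn a [scenario()].
#' @param discovery result of [run_discovery()].
#' @param seed integer seed.
#' @return tibble of stage records C1-C4.
#' @export
run_improvement <- function(world, scn, discovery, seed = 1) {
  cfg <- world$config
  map <- world$map
  panel <- world$panel
  hybrid <- world$elite$elite_hybrid
  units <- discovery$units
  if (length(units) != cfg$n_units) stop("improvement needs exactly ",
                                         cfg$n_units, " starting individuals")
  eq <- discovery$eq
  trait_cal <- discovery$trait
  with_seed(seed, {
    recs <- vector("list", cfg$improvement_cycles)
    for (cyc in seq_len(cfg$improvement_cycles)) {
      seeds <- random_mate(units, cfg$seeds_per_cycle_plant, map)
      geno <- gbs_genotype(seeds, discovery$platform, discovery$markers, panel)
      ebv <- predict_ebv(eq, geno)
      seed_tbv <- tbv(seeds, world$trait, panel)
      top <- order(ebv, decreasing = TRUE)[seq_len(cfg$n_units)]
      units <- seeds[top]
      recs[[cyc]] <- stage_record(paste0("C", cyc), units,
                                  accuracy(ebv, seed_tbv), world)
      if (scn$n_synthetic_phenotypes > 0) {
        rest <- setdiff(seq_along(seeds), top)
        phen <- sample(rest, min(scn$n_synthetic_phenotypes, length(rest)))
        tc <- lapply(seeds[phen], function(s) cross(s, hybrid, map))
        yph <- tbv(tc, world$trait, panel) +
          rnorm(length(phen), 0, trait_cal$sigma_e)
        new_eq <- retrain_on_cycle(geno$dosage[phen, , drop = FALSE], yph,
                                   scn$h2, cycle = paste0("C", cyc))
        if (!inherits(new_eq, "no_update")) eq <- new_eq
      }
    }
    do.call(rbind, recs)
  })
}

#' Run one scenario end to end
#'
#' @param world a `sim_world` matching the scenario's Ne and F.
#' @param scn a [scenario()].
#' @param seed integer seed.
#' @return tibble of 7 stage records (T, A, S, C1-C4).
#' @export
run_scenario <- function(world, scn, seed = 1) {
  if (world$Ne != scn$Ne || world$F_within != scn$F_within) {
    stop("world (Ne = ", world$Ne, ", F = ", world$F_within,
         ") does not match the scenario's genetic parameters")
  }
  s <- derive_seeds(seed, 2)
  disc <- run_discovery(world, scn, seed = s[1])
  rbind(disc$records, run_improvement(world, scn, disc, seed = s[2]))
}

#' Run a set of scenarios over replicates
#'
#' Worlds are shared across scenarios that have the same genetic
#' parameters (Ne, F) within a replicate; logistical factors and
#' heritability vary downstream of the world. Seeds derive
#' deterministically from `master_seed`, so a rerun reproduces the
#' record table exactly.
#'
#' @param scenarios a tibble as returned by [scenario_grid()] (or a
#'   filtered subset).
#' @param n_replicates replicates per scenario (study conditions: 10).
#' @param master_seed integer master seed.
#' @param config a [default_config()] list; its `scale` entry shrinks
#'   population sizes for desk runs while preserving factor levels.
#' @param strict passed to [scenario()]; set `FALSE` to allow factor
#'   levels outside the study grid.
#' @param verbose print progress to stderr.
#' @return tibble of stage records, one row per (scenario, replicate,
#'   stage), with the design factors and run provenance attached as
#'   columns and attributes.
#' @export
run_grid <- function(scenarios = scenario_grid(), n_replicates = 10,
                     master_seed = 1, config = default_config(),
                     strict = TRUE, verbose = FALSE) {
  if (anyDuplicated(scenarios$scenario_id)) stop("duplicate scenario ids")
  worlds <- new.env(parent = emptyenv())
  world_seeds <- derive_seeds(master_seed, 1000L)
  run_seeds <- derive_seeds(master_seed + 1, nrow(scenarios) * n_replicates)
  out <- vector("list", nrow(scenarios) * n_replicates)
  k <- 0L
  genetics <- unique(scenarios[, c("Ne", "F_within")])
  for (rep in seq_len(n_replicates)) {
    for (gi in seq_len(nrow(genetics))) {
      key <- paste(rep, genetics$Ne[gi], genetics$F_within[gi], sep = "_")
      sub <- scenarios[scenarios$Ne == genetics$Ne[gi] &
                         scenarios$F_within == genetics$F_within[gi], ]
      if (nrow(sub) == 0) next
      if (!exists(key, envir = worlds)) {
        wseed <- world_seeds[(rep - 1L) * 20L + gi]
        assign(key, build_world(genetics$Ne[gi], genetics$F_within[gi],
                                config, seed = wseed), envir = worlds)
      }
      world <- get(key, envir = worlds)
      for (si in seq_len(nrow(sub))) {
        row <- sub[si, ]
        scn <- scenario(row$approach, row$Ne, row$F_within, row$h2,
                        row$platform, row$seeds_per_landrace,
                        row$n_selected_landraces,
                        row$tested_seeds_per_landrace,
                        row$n_synthetic_phenotypes, strict = strict)
        idx <- which(scenarios$scenario_id == row$scenario_id)
        rseed <- run_seeds[(idx - 1L) * n_replicates + rep]
        if (verbose) {
          message("scenario ", row$scenario_id, " replicate ", rep)
        }
        rec <- run_scenario(world, scn, seed = rseed)
        k <- k + 1L
        out[[k]] <- cbind(
          tibble::as_tibble(row[rep(1, nrow(rec)), ]),
          replicate = rep, rec
        )
      }
    }
    # Worlds are per replicate; drop them before the next one.
    rm(list = ls(envir = worlds), envir = worlds)
  }
  res <- tibble::as_tibble(do.call(rbind, out[seq_len(k)]))
  attr(res, "provenance") <- list(master_seed = master_seed,
                                  scale = config$scale,
                                  config_hash = config_hash(config))
  res
}
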