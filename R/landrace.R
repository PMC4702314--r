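#' Assemble landrace accessions from the founder panel
#'
#' Each accession is founded from a small random subset of founder
#' haplotypes and then propagated as a finite pool under mixed
#' selfing/outcrossing. The selfing rate `s = 2F/(1+F)` is chosen so
#' the equilibrium inbreeding coefficient (excess homozygosity relative
#' to the accession's own allele frequencies) equals `target_F`; the
#' pool converges geometrically, so the default generation count is
#' well past equilibrium for any `F < 1`.
#'
#' @param panel a `founder_panel`.
#' @param n_landraces number of accessions (study conditions: 3,000).
#' @param target_F target within-accession inbreeding in `[0, 1)`.
#' @param pool_size plants maintained per accession per generation.
#' @param founders_per_accession founder haplotypes per accession.
#' @param generations propagation generations (capped at 20).
#' @param seed integer seed.
#' @return list of accessions; each has `accession_id`, `pool` (list of
#'   individuals), `founder_haps`, and `realized_F`.
#' @export
found_landraces <- function(panel, n_landraces, target_F, pool_size = 20,
                            founders_per_accession = 4, generations = 10,
                            seed = 1) {
  stopifnot(n_landraces >= 1, target_F >= 0, target_F < 1, pool_size >= 2)
  if (generations > 20) stop("generations capped at 20")
  map <- panel$map
  s <- selfing_rate_for(target_F, pool_size)
  f_reached <- selfing_F_after(2 * target_F / (1 + target_F), generations)
  if (abs(f_reached - target_F) > 0.02) {
    stop(sprintf(
      "target F = %.2f unreachable within %d generations (realized %.3f)",
      target_F, generations, f_reached))
  }
  with_seed(seed, {
    lapply(seq_len(n_landraces), function(a) {
      fh <- sample(panel$founder_ids, founders_per_accession, replace = FALSE)
      pool <- lapply(seq_len(pool_size), function(i) {
        h <- sample(fh, 2, replace = FALSE)
        founder_individual(h[1], h[2], map, role = "landrace")
      })
      for (g in seq_len(generations)) {
        pool <- mate_pool(pool, pool_size, s, map)
      }
      list(accession_id = a, pool = pool, founder_haps = fh,
           realized_F = NA_real_)
    })
  })
}

# Deterministic recursion F_t = s (1 + F_{t-1}) / 2 from F_0 = 0.
selfing_F_after <- function(s, generations) {
  f <- 0
  for (g in seq_len(generations)) f <- s * (1 + f) / 2
  f
}

# Selfing rate whose mixed-mating equilibrium hits the target F,
# correcting for the heterozygote excess (about 1/(2N-1)) that
# enforced outcrossing induces in a pool of N plants:
# F = s(1+F)/2 - (1-s)d  =>  s = (F + d) / ((1+F)/2 + d).
selfing_rate_for <- function(target_F, pool_size) {
  d <- 1 / (2 * pool_size - 1)
  (target_F + d) / ((1 + target_F) / 2 + d)
}

# One generation of mixed selfing (probability s) / outcrossing.
mate_pool <- function(pool, n_offspring, s, map) {
  n <- length(pool)
  lapply(seq_len(n_offspring), function(i) {
    m <- sample.int(n, 1)
    if (runif(1) < s || n == 1) {
      f <- m
    } else {
      f <- sample.int(n - 1L, 1)
      f <- f + (f >= m)
    }
    cross(pool[[m]], pool[[f]], map, role = "landrace")
  })
}

#' Sample seeds from an accession
#'
#' Seeds are produced by the accession's own mating system (the same
#' mixed selfing/outcrossing used during propagation), so seed-level
#' inbreeding matches the accession's equilibrium.
#'
#' @param accession one accession from [found_landraces()].
#' @param n number of seeds.
#' @param map a `genome_map`.
#' @param target_F the accession's target inbreeding (sets the selfing
#'   rate).
#' @param role role tag for the seeds.
#' @return list of `n` seed individuals.
#' @export
accession_seeds <- function(accession, n, map, target_F, role = "landrace_seed") {
  s <- selfing_rate_for(target_F, length(accession$pool))
  seeds <- mate_pool(accession$pool, n, s, map)
  for (i in seq_along(seeds)) seeds[[i]]$role <- role
  seeds
}

#' Realized inbreeding of a set of individuals
#'
#' Estimated as excess homozygosity relative to the group's own allele
#' frequencies: `F = 1 - mean(H_obs) / mean(H_exp)` over sites
#' segregating within the group, with `H_exp = 2p(1-p) * 2n/(2n-1)`
#' (small-sample corrected).
#'
#' @param inds list of individuals.
#' @param panel a `founder_panel`.
#' @param loci locus indices used for the estimate (default: all).
#' @return the estimated inbreeding coefficient.
#' @export
realized_F <- function(inds, panel, loci = seq_len(panel$map$n_loci)) {
  n <- length(inds)
  g <- dosage_at(inds, loci, panel)
  p <- colMeans(g) / 2
  seg <- p > 0 & p < 1
  if (!any(seg)) return(NA_real_)
  h_obs <- colMeans(g[, seg, drop = FALSE] == 1)
  h_exp <- 2 * p[seg] * (1 - p[seg]) * (2 * n) / (2 * n - 1)
  1 - mean(h_obs) / mean(h_exp)
}
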