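#' Breed the elite hybrid and its parental inbreds
#'
#' Two closed sub-populations are drawn from the founder panel and
#' improved by truncation selection on TBV, after which the best plant
#' of each is fixed as a doubled haploid. The elite hybrid is the F1 of
#' the two inbreds: its two haplotypes are exact copies of one
#' haplotype of each inbred. Selection enriches the elite genome for
#' favorable QTL alleles in marker contexts that differ from the
#' landrace linkage phase, which is what later degrades landrace-trained
#' predictions on segregating elite x landrace material.
#'
#' @param panel a `founder_panel`.
#' @param trait a `trait_architecture` (calibration not required).
#' @param n_selection_generations generations of truncation selection
#'   (default 5).
#' @param subpop_size plants per closed sub-population (default 50).
#' @param top_frac selected proportion per generation (default 0.1).
#' @param seed integer seed.
#' @param min_tbv if given, the hybrid TBV must strictly exceed it
#'   (e.g. the landrace mean TBV); otherwise an error is raised.
#' @return an object of class `elite_package` with `elite_inbred_A`,
#'   `elite_inbred_B`, and `elite_hybrid`.
#' @export
breed_elite <- function(panel, trait, n_selection_generations = 5,
                        subpop_size = 50, top_frac = 0.1, seed = 1,
                        min_tbv = NULL) {
  map <- panel$map
  n_hap <- length(panel$founder_ids)
  with_seed(seed, {
    draw <- if (n_hap >= 4 * subpop_size) {
      sample(panel$founder_ids, 4 * subpop_size, replace = FALSE)
    } else {
      sample(panel$founder_ids, 4 * subpop_size, replace = TRUE)
    }
    inbreds <- lapply(0:1, function(side) {
      haps <- draw[seq_len(2 * subpop_size) + side * 2 * subpop_size]
      pop <- lapply(seq_len(subpop_size), function(i) {
        founder_individual(haps[2 * i - 1], haps[2 * i], map, role = "elite")
      })
      for (g in seq_len(n_selection_generations)) {
        bv <- tbv(pop, trait, panel)
        n_sel <- max(2L, ceiling(top_frac * length(pop)))
        sel <- pop[order(bv, decreasing = TRUE)[seq_len(n_sel)]]
        pop <- random_mate(sel, ceiling(subpop_size / n_sel), map,
                           role = "elite")[seq_len(subpop_size)]
      }
      bv <- tbv(pop, trait, panel)
      make_dh(pop[[which.max(bv)]], map, role = "elite_inbred")
    })
    hybrid <- new_individual(inbreds[[1]]$org1, inbreds[[2]]$org1,
                             role = "elite_hybrid")
    if (!is.null(min_tbv) && tbv(hybrid, trait, panel) <= min_tbv) {
      stop("elite hybrid TBV does not exceed the landrace mean; ",
           "raise selection intensity or generations")
    }
    structure(list(elite_inbred_A = inbreds[[1]],
                   elite_inbred_B = inbreds[[2]],
                   elite_hybrid = hybrid),
              class = "elite_package")
  })
}
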