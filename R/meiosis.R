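#' Gamete formation with recombination
#'
#' Forms one gamete from a parent under the Haldane model: the
#' crossover count per chromosome is Poisson with mean equal to the
#' chromosome's genetic length in Morgans, crossover positions are
#' uniform, there is no interference and no obligate crossover, and the
#' starting strand is a fair coin. The gamete is returned as a
#' founder-origin track; alleles follow from the founder panel.
#'
#' @param parent an individual.
#' @param map a `genome_map`.
#' @return per-chromosome origin track list (one haplotype).
#' @export
make_gamete <- function(parent, map) {
  gamete_cpp(parent$org1, parent$org2, map$chrom_length_cm)
}

#' Cross two individuals
#'
#' @param mother,father individuals.
#' @param map a `genome_map`.
#' @param role role tag of the offspring.
#' @param id offspring id.
#' @return the offspring individual (one gamete from each parent).
#' @export
cross <- function(mother, father, map, role = "cross", id = NA_integer_) {
  new_individual(make_gamete(mother, map), make_gamete(father, map),
                 role = role, id = id,
                 mother = mother$id, father = father$id)
}

#' Doubled haploid of a parent
#'
#' One gamete is duplicated into both haplotypes, giving a fully
#' homozygous individual.
#'
#' @inheritParams cross
#' @param parent an individual.
#' @return the doubled-haploid individual.
#' @export
make_dh <- function(parent, map, role = "dh", id = NA_integer_) {
  g <- make_gamete(parent, map)
  new_individual(g, g, role = role, id = id,
                 mother = parent$id, father = parent$id)
}

#' Random mating of a set of plants
#'
#' Each plant mothers `n_seeds_per_plant` seeds; the father of each
#' seed is drawn uniformly from the other plants (selfing excluded).
#'
#' @param plants list of >= 2 individuals.
#' @param n_seeds_per_plant seeds per plant.
#' @param map a `genome_map`.
#' @param role role tag for the seeds.
#' @return list of `length(plants) * n_seeds_per_plant` seeds.
#' @export
random_mate <- function(plants, n_seeds_per_plant, map, role = "synthetic") {
  n <- length(plants)
  if (n < 2) stop("random mating needs at least two plants (selfing is not modeled)")
  seeds <- vector("list", n * n_seeds_per_plant)
  k <- 0L
  for (i in seq_len(n)) {
    mates <- sample.int(n - 1L, n_seeds_per_plant, replace = TRUE)
    mates <- mates + (mates >= i)  # skip self
    for (j in seq_len(n_seeds_per_plant)) {
      k <- k + 1L
      seeds[[k]] <- cross(plants[[i]], plants[[mates[j]]], map,
                          role = role, id = k)
    }
  }
  seeds
}
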