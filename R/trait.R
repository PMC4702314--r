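#' Sample a polygenic trait architecture
#'
#' QTL are drawn from the map's QTL locus set and allele-substitution
#' effects of the derived (1) allele are i.i.d. standard normal. The
#' environmental variance is calibrated later, once, from the initial
#' training population (see [calibrate_sigma_e()]), so effects need no
#' rescaling.
#'
#' @param map a `genome_map`.
#' @param n_qtl number of QTL (default: all QTL loci of the map).
#' @param seed integer seed.
#' @return an object of class `trait_architecture` with fields `qtl`
#'   (locus indices), `effects`, and `sigma_e` (NA until calibrated).
#' @export
sample_trait <- function(map, n_qtl = length(map$qtl_index), seed = 1) {
  stopifnot(n_qtl >= 1, n_qtl <= length(map$qtl_index))
  with_seed(seed, {
    qtl <- sort(sample(map$qtl_index, n_qtl))
    structure(list(qtl = qtl, effects = rnorm(n_qtl), sigma_e = NA_real_),
              class = "trait_architecture")
  })
}

#' True breeding values under the additive model
#'
#' TBV is the sum over QTL of allele dosage times the substitution
#' effect.
#'
#' @param inds list of individuals (or one individual).
#' @param trait a `trait_architecture`.
#' @param panel a `founder_panel`.
#' @return numeric vector of TBVs.
#' @export
tbv <- function(inds, trait, panel) {
  if (!is.null(inds$org1)) inds <- list(inds)
  as.numeric(dosage_at(inds, trait$qtl, panel) %*% trait$effects)
}

#' Calibrate the environmental variance from the training population
#'
#' Sets `sigma_e^2 = Var(TBV) * (1 - h2) / h2` so that the testcross
#' heritability in the initial training population equals `h2`. The
#' value is then held fixed for all later phenotyping, including
#' improvement-phase retraining.
#'
#' @param trait a `trait_architecture`.
#' @param training_tbv TBVs of the initial training testcrosses.
#' @param h2 target heritability in `(0, 1]`.
#' @return the trait with `sigma_e` filled in.
#' @export
calibrate_sigma_e <- function(trait, training_tbv, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  trait$sigma_e <- sqrt(var(training_tbv) * (1 - h2) / h2)
  trait
}

#' Testcross an individual to the elite hybrid and phenotype it
#'
#' The testcross is a cross of the candidate to the elite hybrid; its
#' phenotype is the testcross TBV plus normal noise with the calibrated
#' environmental standard deviation.
#'
#' @param parent candidate individual.
#' @param elite_hybrid the elite hybrid individual.
#' @param trait a calibrated `trait_architecture`.
#' @param panel a `founder_panel`.
#' @param stage stage tag recorded with the phenotype.
#' @return list with `testcross` (individual) and `phenotype` (value).
#' @export
testcross_phenotype <- function(parent, elite_hybrid, trait, panel,
                                stage = "T") {
  if (is.na(trait$sigma_e)) stop("sigma_e not calibrated; see calibrate_sigma_e()")
  tc <- cross(parent, elite_hybrid, panel$map, role = "testcross")
  y <- tbv(tc, trait, panel) + rnorm(1, 0, trait$sigma_e)
  list(testcross = tc, phenotype = y, stage = stage)
}
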