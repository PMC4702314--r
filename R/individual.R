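#' @name individuals
#' @title Individuals as founder-origin mosaics
#'
#' @description An individual carries two haplotypes per chromosome,
#' each stored as a piecewise-constant founder-origin track: a vector
#' of segment start positions (cM, first always 0) and the founder
#' haplotype id occupying each segment. Alleles at any locus are read
#' from the founder panel through the track, so allele storage and
#' meiosis never copy allele vectors and identity-by-descent is exact.
NULL

new_individual <- function(org1, org2, role = "founder", id = NA_integer_,
                           mother = NA_integer_, father = NA_integer_) {
  list(org1 = org1, org2 = org2, role = role, id = id,
       mother = mother, father = father)
}

founder_individual <- function(hapA, hapB, map, role = "founder",
                               id = NA_integer_) {
  org <- function(h) {
    lapply(seq_len(map$n_chrom), function(c) list(start = 0, id = as.integer(h)))
  }
  new_individual(org(hapA), org(hapB), role = role, id = id)
}

#' Alleles of one haplotype at a set of loci
#'
#' @param org per-chromosome origin track list of one haplotype.
#' @param loci global locus indices (any order).
#' @param panel a `founder_panel`.
#' @return integer vector of 0/1 alleles, aligned with `loci`.
#' @keywords internal
hap_alleles <- function(org, loci, panel) {
  map <- panel$map
  hap_alleles_cpp(org, map$chrom, map$pos_cm, as.integer(loci), panel$H)
}

#' Dosage matrix of individuals at a set of loci
#'
#' @param inds list of individuals.
#' @param loci global locus indices.
#' @param panel a `founder_panel`.
#' @return numeric matrix, individuals x loci, entries 0/1/2.
#' @export
dosage_at <- function(inds, loci, panel) {
  out <- matrix(0L, nrow = length(inds), ncol = length(loci))
  for (i in seq_along(inds)) {
    out[i, ] <- hap_alleles(inds[[i]]$org1, loci, panel) +
      hap_alleles(inds[[i]]$org2, loci, panel)
  }
  out
}

het_at <- function(inds, loci, panel) {
  out <- matrix(FALSE, nrow = length(inds), ncol = length(loci))
  for (i in seq_along(inds)) {
    out[i, ] <- hap_alleles(inds[[i]]$org1, loci, panel) !=
      hap_alleles(inds[[i]]$org2, loci, panel)
  }
  out
}

validate_track <- function(ind, map) {
  for (org in list(ind$org1, ind$org2)) {
    stopifnot(length(org) == map$n_chrom)
    for (c in seq_len(map$n_chrom)) {
      tr <- org[[c]]
      if (tr$start[1] != 0 || is.unsorted(tr$start, strictly = TRUE) ||
          any(tr$start >= map$chrom_length_cm[c])) {
        stop("malformed origin track on chromosome ", c)
      }
    }
  }
  invisible(TRUE)
}
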