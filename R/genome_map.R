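#' Define a genome map template
#'
#' The genome is modeled on the maize karyotype: `n_chrom` chromosomes
#' with genetic lengths in Morgans. Locus positions are filled in by
#' [simulate_founders()] from the segregating sites of the coalescent
#' sample; the template only fixes the chromosome structure and the
#' per-chromosome locus budget (candidate GBS loci plus QTL).
#'
#' @param n_chrom number of chromosomes (default 10).
#' @param chrom_length_morgan genetic length per chromosome in Morgans,
#'   recycled to `n_chrom` (default 2).
#' @param candidate_loci_per_chrom candidate GBS loci per chromosome.
#'   The default of 10,000 accommodates a 100,000-marker genome-wide
#'   panel; scale down for desk runs.
#' @param n_qtl total number of QTL genome-wide, split evenly across
#'   chromosomes (default 1,000).
#' @return an object of class `genome_map_template`.
#' @export
genome_map_template <- function(n_chrom = 10, chrom_length_morgan = 2,
                                candidate_loci_per_chrom = 10000,
                                n_qtl = 1000) {
  stopifnot(n_chrom >= 1, all(chrom_length_morgan > 0),
            candidate_loci_per_chrom >= 1, n_qtl >= n_chrom)
  structure(list(
    n_chrom = as.integer(n_chrom),
    chrom_length_cm = rep_len(chrom_length_morgan * 100, n_chrom),
    candidate_loci_per_chrom = as.integer(candidate_loci_per_chrom),
    n_qtl = as.integer(n_qtl)
  ), class = "genome_map_template")
}

new_genome_map <- function(template, chrom, pos_cm, qtl_idx) {
  n_loci <- length(pos_cm)
  stopifnot(length(chrom) == n_loci, all(diff(qtl_idx) > 0) || length(qtl_idx) <= 1)
  for (c in seq_len(template$n_chrom)) {
    p <- pos_cm[chrom == c]
    if (any(diff(p) <= 0)) {
      stop("locus positions must be strictly increasing within chromosome ", c)
    }
  }
  cand <- setdiff(seq_len(n_loci), qtl_idx)
  structure(list(
    n_chrom = template$n_chrom,
    chrom_length_cm = template$chrom_length_cm,
    chrom = as.integer(chrom),
    pos_cm = as.numeric(pos_cm),
    n_loci = n_loci,
    qtl_index = as.integer(qtl_idx),
    candidate_marker_index = as.integer(cand),
    loci_by_chrom = split(seq_len(n_loci), factor(chrom, seq_len(template$n_chrom)))
  ), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$n_chrom, " chromosomes, ",
      sum(x$chrom_length_cm) / 100, " Morgans, ",
      x$n_loci, " loci (", length(x$qtl_index), " QTL, ",
      length(x$candidate_marker_index), " candidate markers)\n", sep = "")
  invisible(x)
}
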