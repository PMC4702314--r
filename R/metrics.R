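#' Merit scale of a simulated world
#'
#' Genetic merit is expressed on a scale where the landrace population
#' mean is 0 and the elite hybrid is 1.
#'
#' @param landrace_mean_tbv mean TBV of the landrace population.
#' @param elite_tbv TBV of the elite hybrid.
#' @param landrace_sd_tbv SD of landrace TBVs (used for responses in
#'   genetic standard deviations).
#' @return an object of class `merit_scale`.
#' @export
merit_scale <- function(landrace_mean_tbv, elite_tbv,
                        landrace_sd_tbv = NA_real_) {
  if (elite_tbv == landrace_mean_tbv) {
    stop("elite TBV equals the landrace mean; merit scale undefined")
  }
  structure(list(landrace_mean_tbv = landrace_mean_tbv,
                 elite_tbv = elite_tbv,
                 landrace_sd_tbv = landrace_sd_tbv),
            class = "merit_scale")
}

#' Normalized genetic merit of a germplasm
#'
#' `(mean(TBV) - landrace mean) / (elite TBV - landrace mean)`; the
#' landrace population scores 0 and the elite hybrid 1 by definition.
#'
#' @param tbvs TBVs of the germplasm's individuals.
#' @param scale a [merit_scale()].
#' @return dimensionless merit.
#' @export
normalized_merit <- function(tbvs, scale) {
  (mean(tbvs) - scale$landrace_mean_tbv) /
    (scale$elite_tbv - scale$landrace_mean_tbv)
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between EBV and TBV. Constant vectors make the
#' correlation undefined; `NA` is returned rather than 0.
#'
#' @param ebvs,tbvs aligned numeric vectors (>= 3 pairs).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
accuracy <- function(ebvs, tbvs) {
  stopifnot(length(ebvs) == length(tbvs))
  if (length(ebvs) < 3) stop("at least 3 pairs are required")
  if (sd(ebvs) == 0 || sd(tbvs) == 0) return(NA_real_)
  cor(ebvs, tbvs)
}

#' Accession-level accuracy
#'
#' Correlation across accessions between the mean EBV of the training
#' seeds and the mean TBV of the accession's seeds. Group means vary
#' less than individuals, so this is typically above seed-level
#' accuracy.
#'
#' @param mean_ebv,mean_tbv per-accession means, aligned.
#' @return Pearson correlation.
#' @export
accession_accuracy <- function(mean_ebv, mean_tbv) {
  accuracy(mean_ebv, mean_tbv)
}

#' Identity-by-descent segment kinship with the elite hybrid
#'
#' The genome is partitioned into consecutive bins of `segment_cm`
#' (default 1 cM). For every (germplasm haplotype, elite haplotype)
#' pair, a bin counts as identical when the founder-origin function is
#' identical across the whole bin. Kinship is the mean over bins, the
#' four haplotype pairs, and individuals. An allele-sequence (IBS)
#' mode is available; it inflates kinship when founder diversity is
#' low, because the same haplotype can recur by state.
#'
#' @param inds germplasm individuals (list) or one individual.
#' @param elite an `elite_package` or the elite hybrid individual.
#' @param panel a `founder_panel`.
#' @param segment_cm bin width in cM; must tile every chromosome
#'   exactly.
#' @param mode `"ibd"` (founder-origin identity, default) or `"ibs"`
#'   (allele-sequence identity over the bin's loci).
#' @return kinship in `[0, 1]`.
#' @export
segment_kinship <- function(inds, elite, panel, segment_cm = 1,
                            mode = c("ibd", "ibs")) {
  mode <- match.arg(mode)
  map <- panel$map
  if (any(abs(map$chrom_length_cm / segment_cm -
              round(map$chrom_length_cm / segment_cm)) > 1e-8)) {
    stop("segment grid does not tile the genetic map")
  }
  hybrid <- if (inherits(elite, "elite_package")) elite$elite_hybrid else elite
  if (!is.null(inds$org1)) inds <- list(inds)
  sig_fun <- if (mode == "ibd") {
    function(org) bin_signature(org, map, segment_cm)
  } else {
    function(org) bin_signature_ibs(org, map, segment_cm, panel)
  }
  e1 <- sig_fun(hybrid$org1)
  e2 <- sig_fun(hybrid$org2)
  vals <- vapply(inds, function(ind) {
    s1 <- sig_fun(ind$org1)
    s2 <- sig_fun(ind$org2)
    (mean(s1 == e1) + mean(s1 == e2) + mean(s2 == e1) + mean(s2 == e2)) / 4
  }, numeric(1))
  mean(vals)
}

# Character signature of one haplotype per bin; see bin_signature_cpp.
bin_signature <- function(org, map, segment_cm) {
  bin_signature_cpp(org, map$chrom_length_cm, segment_cm)
}

bin_signature_ibs <- function(org, map, segment_cm, panel) {
  out <- vector("list", map$n_chrom)
  for (c in seq_len(map$n_chrom)) {
    loci <- map$loci_by_chrom[[c]]
    al <- hap_alleles(org, loci, panel)
    n_bin <- round(map$chrom_length_cm[c] / segment_cm)
    bin <- findInterval(map$pos_cm[loci], (seq_len(n_bin) - 1) * segment_cm)
    sig <- vapply(split(al, factor(bin, seq_len(n_bin))), paste,
                  character(1), collapse = "")
    out[[c]] <- sig
  }
  unlist(out)
}

#' Mean heterozygosity over segregating sites
#'
#' Mean over individuals and sites of the indicator that the two
#' alleles differ; the site set is fixed at simulation start (sites
#' segregating in the initial landrace population).
#'
#' @param inds germplasm individuals.
#' @param sites locus indices of the frozen segregating-site set.
#' @param panel a `founder_panel`.
#' @return heterozygosity in `[0, 1]`.
#' @export
heterozygosity <- function(inds, sites, panel) {
  if (!is.null(inds$org1)) inds <- list(inds)
  mean(het_at(inds, sites, panel))
}

#' Response to selection in genetic standard deviations
#'
#' The gain of a germplasm over the landrace mean, expressed in units
#' of the landrace additive genetic standard deviation (GSD), plus the
#' per-season rate under a configurable seasons map (the program
#' bookkeeping of seasons per stage is a reporting convention, not a
#' simulation quantity).
#'
#' @param final_mean_tbv mean TBV of the final germplasm.
#' @param scale a [merit_scale()] with `landrace_sd_tbv` set.
#' @param seasons number of seasons the program occupied.
#' @return list with `gsd_total` and `gsd_per_season`.
#' @export
response_in_gsd <- function(final_mean_tbv, scale, seasons) {
  stopifnot(!is.na(scale$landrace_sd_tbv), seasons > 0)
  total <- (final_mean_tbv - scale$landrace_mean_tbv) / scale$landrace_sd_tbv
  list(gsd_total = total, gsd_per_season = total / seasons)
}
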