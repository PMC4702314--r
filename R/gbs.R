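#' Define a GBS genotyping platform
#'
#' The two study platforms are high-coverage GBS with 10,000 markers
#' (GBS10x@10K) and low-coverage GBS with 100,000 markers (GBS1x@100K).
#' `platform_preset()` returns either, with marker counts scalable for
#' desk runs.
#'
#' @param n_markers marker panel size.
#' @param coverage mean sequencing depth per locus per individual.
#' @param error_rate per-read allele miscall probability (default 0.005).
#' @param name platform label.
#' @return an object of class `gbs_platform`.
#' @export
gbs_platform <- function(n_markers, coverage, error_rate = 0.005,
                         name = sprintf("GBS%gx@%d", coverage, n_markers)) {
  stopifnot(n_markers >= 1, coverage > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(n_markers = as.integer(n_markers), coverage = coverage,
                 error_rate = error_rate, name = name),
            class = "gbs_platform")
}

#' @rdname gbs_platform
#' @param preset `"GBS10x@10K"` or `"GBS1x@100K"`.
#' @param scale population-scale factor applied to the marker count.
#' @export
platform_preset <- function(preset = c("GBS10x@10K", "GBS1x@100K"),
                            scale = 1, error_rate = 0.005) {
  preset <- match.arg(preset)
  if (preset == "GBS10x@10K") {
    gbs_platform(round(10000 * scale), 10, error_rate, name = preset)
  } else {
    gbs_platform(round(100000 * scale), 1, error_rate, name = preset)
  }
}

#' Select a marker panel approximately uniform on the genetic map
#'
#' Marker counts per chromosome are proportional to genetic length
#' (largest-remainder rounding) and markers are sampled uniformly among
#' the candidate loci of each chromosome. QTL are never candidates.
#'
#' @param map a `genome_map`.
#' @param panel_size number of markers.
#' @return sorted vector of global locus indices.
#' @export
select_marker_panel <- function(map, panel_size) {
  cand <- map$candidate_marker_index
  if (panel_size > length(cand)) {
    stop("panel_size (", panel_size, ") exceeds the ", length(cand),
         " candidate marker loci")
  }
  share <- map$chrom_length_cm / sum(map$chrom_length_cm) * panel_size
  n_c <- floor(share)
  rem <- panel_size - sum(n_c)
  if (rem > 0) {
    up <- order(share - n_c, decreasing = TRUE)[seq_len(rem)]
    n_c[up] <- n_c[up] + 1
  }
  cand_chrom <- map$chrom[cand]
  sort(unlist(lapply(seq_len(map$n_chrom), function(c) {
    pool <- cand[cand_chrom == c]
    if (n_c[c] > length(pool)) stop("chromosome ", c, " has too few candidates")
    if (n_c[c] == length(pool)) pool else sample(pool, n_c[c])
  })))
}

#' Simulate GBS genotypes as posterior-mean dosages
#'
#' Per individual and marker, the read count is Poisson(coverage) and
#' derived-allele reads are binomial given the true genotype adjusted
#' by the per-read error rate. The reported dosage is the posterior
#' mean of the genotype given the reads under a Hardy-Weinberg prior at
#' the cohort's current allele frequency. Markers with zero reads are
#' flagged missing and mean-imputed to twice the allele frequency, so
#' the ridge design matrix stays complete.
#'
#' @param inds list of individuals.
#' @param platform a `gbs_platform`.
#' @param markers marker locus indices (from [select_marker_panel()]).
#' @param panel a `founder_panel`.
#' @return an object of class `genotype_matrix`: list with `dosage`
#'   (individuals x markers, values in `[0, 2]`), `missing` (logical
#'   matrix), `markers`, `platform`, and `freq` (cohort allele
#'   frequencies used for prior and imputation).
#' @export
gbs_genotype <- function(inds, platform, markers, panel) {
  if (length(inds) == 0) stop("empty individual list")
  g <- dosage_at(inds, markers, panel)
  n <- nrow(g)
  m <- ncol(g)
  p <- colMeans(g) / 2
  e <- platform$error_rate

  r <- matrix(rpois(n * m, platform$coverage), n, m)
  q_true <- (g / 2) * (1 - e) + (1 - g / 2) * e
  k <- matrix(rbinom(n * m, as.vector(r), as.vector(q_true)), n, m)

  pm <- matrix(p, n, m, byrow = TRUE)
  # Binomial coefficients cancel in the posterior, so likelihoods are
  # plain q^k (1-q)^(r-k) with q in {e, 1/2, 1-e} per genotype class.
  e2 <- max(e, 1e-12)
  le <- log(e2)
  lc <- log1p(-e2)
  w0 <- exp(k * le + (r - k) * lc) * (1 - pm)^2
  w1 <- exp(r * log(0.5)) * 2 * pm * (1 - pm)
  w2 <- exp(k * lc + (r - k) * le) * pm^2
  dosage <- (w1 + 2 * w2) / (w0 + w1 + w2)

  miss <- r == 0L
  dosage[miss] <- (2 * pm)[miss]

  structure(list(dosage = dosage, missing = miss,
                 markers = as.integer(markers), platform = platform,
                 freq = p),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " markers (", x$platform$name, "), ",
      round(100 * mean(x$missing), 1), "% missing\n", sep = "")
  invisible(x)
}
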