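#' Pedigree table of a set of individuals
#'
#' @param inds list of individuals.
#' @return tibble with id, mother, father, type.
#' @export
pedigree_table <- function(inds) {
  tibble::tibble(
    id = vapply(inds, function(i) as.integer(i$id %||% NA_integer_), integer(1)),
    mother = vapply(inds, function(i) as.integer(i$mother %||% NA_integer_), integer(1)),
    father = vapply(inds, function(i) as.integer(i$father %||% NA_integer_), integer(1)),
    type = vapply(inds, function(i) i$role, character(1))
  )
}

#' Export a genotype matrix to CSV
#'
#' One row per individual, one column per marker (named by global
#' locus index); missing entries are written empty.
#'
#' @param geno a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_genotypes_csv <- function(geno, path) {
  d <- as.data.frame(geno$dosage)
  names(d) <- paste0("m", geno$markers)
  d[geno$missing] <- NA
  write.csv(cbind(individual = seq_len(nrow(d)), d), path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' Export genotypes to a minimal VCF
#'
#' Biallelic, phased where truth is exported, one contig per
#' chromosome. POS is the genetic position in cM times 1e5, rounded to
#' an integer: coordinates are genetic, not physical, and the header
#' says so. Dosages go to the DS FORMAT field.
#'
#' @param inds list of individuals (true phased genotypes) or a
#'   `genotype_matrix` (dosages only).
#' @param loci locus indices to export (for individuals).
#' @param panel a `founder_panel`.
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
export_vcf <- function(inds, loci, panel, path) {
  map <- panel$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=prebreedsim",
    "##INFO=<ID=GP,Number=0,Type=Flag,Description=\"Positions are genetic (cM x 1e5), not physical\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the derived allele\">",
    paste0("##contig=<ID=chr", seq_len(map$n_chrom), ",length=",
           as.integer(map$chrom_length_cm * 1e5 + 1), ">")
  ), con)
  if (inherits(inds, "genotype_matrix")) {
    geno <- inds
    loci <- geno$markers
    n <- nrow(geno$dosage)
    gt <- matrix("./.", n, length(loci))
    ds <- geno$dosage
  } else {
    n <- length(inds)
    h1 <- t(vapply(inds, function(i) hap_alleles(i$org1, loci, panel),
                   integer(length(loci))))
    h2 <- t(vapply(inds, function(i) hap_alleles(i$org2, loci, panel),
                   integer(length(loci))))
    gt <- matrix(paste0(h1, "|", h2), n, length(loci))
    ds <- h1 + h2
  }
  ids <- paste0("ind", seq_len(n))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  for (j in seq_along(loci)) {
    l <- loci[j]
    fields <- paste(gt[, j], format(round(ds[, j], 3), trim = TRUE), sep = ":")
    writeLines(paste(c(paste0("chr", map$chrom[l]),
                       as.integer(round(map$pos_cm[l] * 1e5)),
                       paste0("locus", l), "A", "T", ".", "PASS", "GP",
                       "GT:DS", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Export an accession table to CSV
#'
#' @param accessions list from [found_landraces()].
#' @param panel a `founder_panel`.
#' @param path output path.
#' @param loci loci used for the realized-F estimate (default: a
#'   deterministic subset of up to 2,000).
#' @return `path`, invisibly.
#' @export
export_accessions_csv <- function(accessions, panel, path,
                                  loci = NULL) {
  if (is.null(loci)) {
    n <- panel$map$n_loci
    loci <- unique(as.integer(seq(1, n, length.out = min(2000, n))))
  }
  d <- do.call(rbind, lapply(accessions, function(a) {
    data.frame(accession_id = a$accession_id,
               n_members = length(a$pool),
               founder_haps = paste(a$founder_haps, collapse = ";"),
               realized_F = realized_F(a$pool, panel, loci))
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
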