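#' Simulate founder haplotypes under the neutral coalescent
#'
#' Draws `n_haplotypes` haplotypes per chromosome from the standard
#' neutral coalescent with recombination at effective population size
#' `Ne` (msprime backend, invoked as a subprocess). Segregating sites
#' passing a minor-allele-frequency filter are thinned uniformly at
#' random to the per-chromosome locus budget of the map template, and
#' the QTL subset is drawn uniformly among the retained loci, disjoint
#' from the candidate GBS markers. Alleles are coded 0 (ancestral) / 1
#' (derived).
#'
#' @param template a [genome_map_template()].
#' @param Ne effective population size (the study conditions use 1,000
#'   or 100,000; any positive value is accepted).
#' @param n_haplotypes number of founder haplotypes (>= 2).
#' @param seed integer seed; identical seeds give identical panels.
#' @param mutation_rate per-bp mutation rate of the coalescent sample
#'   (1 cM is represented as 10 kb). The default 1e-6 comfortably meets
#'   the default locus budget at Ne = 1,000; it is recorded in the
#'   panel metadata.
#' @param maf_min minimum minor allele frequency for a segregating site
#'   to enter the locus pool (default 0.05).
#' @return an object of class `founder_panel` with fields `map` (the
#'   completed [genome_map]), `H` (haplotype-by-locus 0/1 matrix),
#'   `founder_ids`, `Ne` and `meta`.
#' @export
simulate_founders <- function(template, Ne, n_haplotypes, seed,
                              mutation_rate = 1e-6, maf_min = 0.05) {
  stopifnot(inherits(template, "genome_map_template"),
            Ne > 0, n_haplotypes >= 2)
  seeds <- derive_seeds(seed, template$n_chrom + 2L)
  budget_qtl <- qtl_per_chrom(template)
  budgets <- template$candidate_loci_per_chrom + budget_qtl

  py <- Sys.which("python")
  if (py == "") stop("python interpreter not found on PATH")
  script <- system.file("python", "founder_sim.py", package = "prebreedsim")
  stopifnot(nzchar(script))

  prefix <- tempfile("founders")
  params <- list(
    Ne = Ne, n_haplotypes = n_haplotypes, mutation_rate = mutation_rate,
    maf_min = maf_min, loci_per_chrom = budgets,
    chrom_length_cm = template$chrom_length_cm,
    chrom_seeds = seeds[seq_len(template$n_chrom)],
    thin_seed = seeds[template$n_chrom + 1L],
    out_prefix = prefix
  )
  param_path <- paste0(prefix, "_params.json")
  jsonlite::write_json(params, param_path, auto_unbox = TRUE, digits = NA)
  on.exit(unlink(paste0(prefix, c("_params.json", "_pos.txt", "_hap.txt",
                                  "_meta.json"))), add = TRUE)

  status <- suppressWarnings(system2(py, c(script, shQuote(param_path)),
                                     stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0L
  if (code != 0L) {
    stop("founder simulation failed:\n", paste(status, collapse = "\n"))
  }

  pos_tab <- matrix(scan(paste0(prefix, "_pos.txt"), what = numeric(),
                         quiet = TRUE), ncol = 2, byrow = TRUE)
  chrom <- as.integer(pos_tab[, 1])
  pos_cm <- pos_tab[, 2]
  H <- matrix(scan(paste0(prefix, "_hap.txt"), what = integer(),
                   quiet = TRUE), nrow = n_haplotypes, byrow = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))

  qtl_idx <- with_seed(seeds[template$n_chrom + 2L], {
    sort(unlist(lapply(seq_len(template$n_chrom), function(c) {
      loci <- which(chrom == c)
      sample(loci, budget_qtl[c])
    })))
  })
  map <- new_genome_map(template, chrom, pos_cm, qtl_idx)

  structure(list(
    map = map,
    H = H,
    founder_ids = seq_len(n_haplotypes),
    Ne = Ne,
    meta = c(meta, list(seed = seed))
  ), class = "founder_panel")
}

qtl_per_chrom <- function(template) {
  base <- template$n_qtl %/% template$n_chrom
  extra <- template$n_qtl %% template$n_chrom
  base + as.integer(seq_len(template$n_chrom) <= extra)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel> ", length(x$founder_ids), " haplotypes, Ne = ",
      x$Ne, ", ", x$map$n_loci, " loci\n", sep = "")
  invisible(x)
}
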