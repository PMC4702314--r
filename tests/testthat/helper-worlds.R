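# Shared fixtures, built once per test run and cached. All fixtures
# are generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Desk-scale world: 60 accessions, 2,020 loci, 80 founder haplotypes.
tiny_config <- function() default_config(scale = 0.02)

tiny_world <- function() {
  cached_fixture("tiny_world", build_world(1000, 0.3, tiny_config(), seed = 42))
}

tiny_panel <- function() tiny_world()$panel

# Small standalone panel on a short two-chromosome map, for meiosis
# and genotyping unit tests.
toy_panel <- function() {
  cached_fixture("toy_panel", {
    tpl <- genome_map_template(2, 0.5, candidate_loci_per_chrom = 60,
                               n_qtl = 10)
    simulate_founders(tpl, 500, 80, seed = 11)
  })
}

# Panel with independent loci (no LD), for closed-form variance and
# heterozygosity checks: haplotypes are i.i.d. Bernoulli draws.
le_panel <- function(n_hap = 200, n_loci = 400, seed = 3) {
  cached_fixture(paste0("le_panel_", n_hap, "_", n_loci, "_", seed), {
    tpl <- genome_map_template(2, 1, candidate_loci_per_chrom = n_loci / 2 - 5,
                               n_qtl = 10)
    set.seed(seed)
    chrom <- rep(1:2, each = n_loci / 2)
    pos <- rep(sort(runif(n_loci / 2, 0, 100)), 2)
    qtl <- sort(c(sample(which(chrom == 1), 5), sample(which(chrom == 2), 5)))
    map <- prebreedsim:::new_genome_map(tpl, chrom, pos, qtl)
    p <- runif(n_loci, 0.1, 0.9)
    H <- matrix(rbinom(n_hap * n_loci, 1, rep(p, each = n_hap)), n_hap, n_loci)
    structure(list(map = map, H = H, founder_ids = seq_len(n_hap),
                   Ne = NA, meta = list(synthetic = TRUE)),
              class = "founder_panel")
  })
}

# Minimal map stub when only chromosome structure matters.
bare_map <- function(n_chrom = 1, length_cm = 100) {
  list(n_chrom = n_chrom, chrom_length_cm = rep(length_cm, n_chrom))
}

founder_ind <- function(hapA, hapB, panel, role = "founder", id = NA_integer_) {
  prebreedsim:::founder_individual(hapA, hapB, panel$map, role = role, id = id)
}
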