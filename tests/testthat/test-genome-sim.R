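test_that("founder simulation is deterministic and meets its locus budget", {
  tpl <- genome_map_template(2, 0.2, candidate_loci_per_chrom = 40, n_qtl = 4)
  p1 <- simulate_founders(tpl, 300, 50, seed = 7)
  p2 <- simulate_founders(tpl, 300, 50, seed = 7)
  expect_identical(p1$H, p2$H)
  expect_identical(p1$map$pos_cm, p2$map$pos_cm)
  expect_identical(p1$map$qtl_index, p2$map$qtl_index)

  expect_equal(p1$map$n_loci, 2 * (40 + 2))
  expect_length(intersect(p1$map$qtl_index, p1$map$candidate_marker_index), 0)
  for (c in 1:2) {
    expect_true(all(diff(p1$map$pos_cm[p1$map$chrom == c]) > 0))
  }
  # all loci polymorphic at the MAF threshold
  freq <- colMeans(p1$H)
  expect_true(all(freq >= 0.05 & freq <= 0.95))
})

test_that("an unreachable locus budget fails naming the shortfall", {
  tpl <- genome_map_template(1, 0.02, candidate_loci_per_chrom = 5000, n_qtl = 1)
  expect_error(simulate_founders(tpl, 100, 20, seed = 1, mutation_rate = 1e-7),
               "segregating sites")
})

test_that("diversity and adjacent-locus LD are ordered in Ne", {
  tpl <- genome_map_template(1, 0.02, candidate_loci_per_chrom = 100, n_qtl = 2)
  lo <- simulate_founders(tpl, 1000, 200, seed = 5)
  hi <- simulate_founders(tpl, 100000, 200, seed = 5)
  expect_gte(unlist(hi$meta$raw_segregating_sites),
             unlist(lo$meta$raw_segregating_sites))
  r2 <- function(H) {
    mean(vapply(seq_len(ncol(H) - 1),
                function(j) cor(H[, j], H[, j + 1])^2, numeric(1)))
  }
  expect_gt(r2(lo$H), r2(hi$H))
})

test_that("founder individuals reproduce panel haplotypes exactly", {
  panel <- toy_panel()
  ind <- founder_ind(3, 17, panel)
  loci <- seq_len(panel$map$n_loci)
  expect_identical(prebreedsim:::hap_alleles(ind$org1, loci, panel),
                   as.integer(panel$H[3, ]))
  expect_identical(prebreedsim:::hap_alleles(ind$org2, loci, panel),
                   as.integer(panel$H[17, ]))
  expect_true(prebreedsim:::validate_track(ind, panel$map))
})

test_that("accessions reach their target inbreeding within 0.05 on average", {
  panel <- toy_panel()
  for (f in c(0.3, 0.9)) {
    acc <- found_landraces(panel, 50, f, pool_size = 20, seed = 20 + 10 * f)
    fhat <- vapply(acc, function(a) realized_F(a$pool, panel), numeric(1))
    expect_lt(abs(mean(fhat, na.rm = TRUE) - f), 0.05)
  }
})

test_that("inbreeding lowers heterozygosity and F = 0 stays near zero", {
  panel <- toy_panel()
  sites <- seq_len(panel$map$n_loci)
  acc_lo <- found_landraces(panel, 10, 0.3, seed = 31)
  acc_hi <- found_landraces(panel, 10, 0.9, seed = 31)
  het <- function(accs) {
    mean(vapply(accs, function(a) heterozygosity(a$pool, sites, panel),
                numeric(1)))
  }
  expect_gt(het(acc_lo), het(acc_hi))

  acc0 <- found_landraces(panel, 20, 0, founders_per_accession = 10,
                          pool_size = 20, seed = 32)
  f0 <- mean(vapply(acc0, function(a) realized_F(a$pool, panel), numeric(1)),
             na.rm = TRUE)
  expect_lt(abs(f0), 0.05)
})

test_that("elite inbreds are fixed and the hybrid copies their haplotypes", {
  w <- tiny_world()
  sites <- seq_len(w$map$n_loci)
  expect_equal(heterozygosity(w$elite$elite_inbred_A, sites, w$panel), 0)
  expect_equal(heterozygosity(w$elite$elite_inbred_B, sites, w$panel), 0)
  expect_identical(w$elite$elite_hybrid$org1, w$elite$elite_inbred_A$org1)
  expect_identical(w$elite$elite_hybrid$org2, w$elite$elite_inbred_B$org1)
  expect_gt(tbv(w$elite$elite_hybrid, w$trait, w$panel),
            w$merit$landrace_mean_tbv)
})
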