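test_that("normalized merit matches its definition and is affine-invariant", {
  sc <- merit_scale(2, 8)
  expect_equal(normalized_merit(5, sc), 0.5)
  expect_equal(normalized_merit(c(8, 8), sc), 1)
  expect_equal(normalized_merit(rep(2, 10), sc), 0)
  # shifting or rescaling all TBVs (scale included) leaves merit unchanged
  tbvs <- rnorm(20, 5)
  for (a in c(-3, 7)) {
    sc2 <- merit_scale(2 + a, 8 + a)
    expect_equal(normalized_merit(tbvs + a, sc2), normalized_merit(tbvs, sc))
  }
  sc3 <- merit_scale(2 * 4, 8 * 4)
  expect_equal(normalized_merit(tbvs * 4, sc3), normalized_merit(tbvs, sc))
  expect_error(merit_scale(3, 3), "undefined")
})

test_that("accuracy is a guarded Pearson correlation", {
  x <- rnorm(50)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(-x, x), -1)
  expect_true(is.na(accuracy(rep(1, 10), rnorm(10))))
  expect_error(accuracy(1:2, 1:2), "3")
  set.seed(41)
  expect_lt(abs(accuracy(rnorm(1000), rnorm(1000))), 0.1)
  expect_equal(accession_accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
})

test_that("segment kinship: self, clone, and disjoint-founder cases", {
  panel <- toy_panel()
  set.seed(43)
  # inbreds with recombinant but fixed haplotypes, as DH fixation gives
  inbA <- make_dh(cross(founder_ind(1, 2, panel), founder_ind(3, 4, panel),
                        panel$map), panel$map)
  inbB <- make_dh(cross(founder_ind(5, 6, panel), founder_ind(7, 8, panel),
                        panel$map), panel$map)
  elite <- structure(list(elite_inbred_A = inbA, elite_inbred_B = inbB,
                          elite_hybrid = prebreedsim:::new_individual(
                            inbA$org1, inbB$org1, role = "elite_hybrid")),
                     class = "elite_package")
  hyb <- elite$elite_hybrid
  # the hybrid's haplotypes derive from disjoint founders: 2 of 4 pairs match
  expect_equal(segment_kinship(hyb, elite, panel), 0.5)
  clone <- prebreedsim:::new_individual(hyb$org1, hyb$org2)
  expect_equal(segment_kinship(clone, elite, panel), 0.5)
  doubled <- prebreedsim:::new_individual(hyb$org1, hyb$org1)
  expect_equal(segment_kinship(doubled, elite, panel), 0.5)
  stranger <- founder_ind(9, 10, panel)
  expect_equal(segment_kinship(stranger, elite, panel), 0)
  expect_error(segment_kinship(stranger, elite, panel, segment_cm = 0.3),
               "tile")
})

test_that("heterozygosity of DH, F1 and random-mating populations", {
  panel <- toy_panel()
  sites <- seq_len(panel$map$n_loci)
  set.seed(42)
  parent <- founder_ind(1, 2, panel)
  expect_equal(heterozygosity(make_dh(parent, panel$map), sites, panel), 0)
  f1 <- cross(founder_ind(3, 3, panel), founder_ind(4, 4, panel), panel$map)
  expect_equal(heterozygosity(f1, sites, panel),
               mean(panel$H[3, ] != panel$H[4, ]))
  # random union of panel haplotypes ~ Hardy-Weinberg expectation
  le <- le_panel()
  le_sites <- seq_len(le$map$n_loci)
  inds <- lapply(1:400, function(i) founder_ind(sample(200, 1),
                                                sample(200, 1), le))
  p <- colMeans(le$H)
  expected <- mean(2 * p * (1 - p))
  expect_lt(abs(heterozygosity(inds, le_sites, le) - expected) / expected, 0.05)
})

test_that("responses convert to genetic standard deviations per season", {
  sc <- merit_scale(0, 1, landrace_sd_tbv = 1)
  r <- response_in_gsd(2.52, sc, seasons = 6)
  expect_equal(r$gsd_total, 2.52)
  expect_equal(r$gsd_per_season, 0.42)
  r2 <- response_in_gsd(2.68, sc, seasons = 9)
  expect_equal(round(r2$gsd_per_season, 2), 0.3)
  expect_equal(response_in_gsd(0, sc, 6)$gsd_total, 0)
})
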