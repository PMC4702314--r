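test_that("a fully homozygous parent transmits its haplotype unchanged", {
  panel <- toy_panel()
  ind <- founder_ind(5, 5, panel)
  set.seed(1)
  loci <- seq_len(panel$map$n_loci)
  for (i in 1:5) {
    g <- make_gamete(ind, panel$map)
    expect_identical(prebreedsim:::hap_alleles(g, loci, panel),
                     as.integer(panel$H[5, ]))
  }
})

test_that("crossover counts follow Poisson(map length in Morgans)", {
  map <- bare_map(1, 100)  # one 1-Morgan chromosome
  parent <- prebreedsim:::founder_individual(1, 2, map)
  set.seed(99)
  n <- 10000
  # with two distinct founder ids every crossover is a visible boundary
  k <- vapply(seq_len(n), function(i) {
    length(make_gamete(parent, map)[[1]]$id) - 1L
  }, integer(1))
  expect_lt(abs(mean(k) - 1), 3 / sqrt(n))  # SE of Poisson(1) mean
  obs <- tabulate(pmin(k, 4) + 1L, nbins = 5)
  pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  expect_gt(chisq.test(obs, p = pr)$p.value, 0.001)
})

test_that("offspring of two inbreds is heterozygous exactly where they differ", {
  panel <- toy_panel()
  a <- founder_ind(1, 1, panel)
  b <- founder_ind(2, 2, panel)
  set.seed(2)
  off <- cross(a, b, panel$map)
  loci <- seq_len(panel$map$n_loci)
  het <- prebreedsim:::het_at(list(off), loci, panel)[1, ]
  expect_identical(het, panel$H[1, ] != panel$H[2, ])
})

test_that("every offspring allele is Mendelian-consistent with its parents", {
  panel <- toy_panel()
  set.seed(3)
  loci <- seq_len(panel$map$n_loci)
  for (i in 1:10) {
    a <- founder_ind(sample(80, 1), sample(80, 1), panel)
    b <- founder_ind(sample(80, 1), sample(80, 1), panel)
    off <- cross(a, b, panel$map)
    o1 <- prebreedsim:::hap_alleles(off$org1, loci, panel)
    o2 <- prebreedsim:::hap_alleles(off$org2, loci, panel)
    pa <- prebreedsim:::dosage_at(list(a), loci, panel)[1, ]
    pb <- prebreedsim:::dosage_at(list(b), loci, panel)[1, ]
    # maternal allele must occur in the mother, paternal in the father
    expect_true(all((pa > 0 | o1 == 0) & (pa < 2 | o1 == 1)))
    expect_true(all((pb > 0 | o2 == 0) & (pb < 2 | o2 == 1)))
  }
})

test_that("expected offspring TBV is the mid-parent value", {
  panel <- toy_panel()
  trait <- sample_trait(panel$map, seed = 5)
  set.seed(6)
  a <- founder_ind(1, 2, panel)
  b <- founder_ind(3, 4, panel)
  mid <- mean(tbv(list(a, b), trait, panel))
  off <- replicate(4000, cross(a, b, panel$map), simplify = FALSE)
  bv <- tbv(off, trait, panel)
  expect_lt(abs(mean(bv) - mid), 3 * sd(bv) / sqrt(length(bv)))
})

test_that("doubled haploids are fully homozygous and unbiased in TBV", {
  panel <- toy_panel()
  trait <- sample_trait(panel$map, seed = 5)
  sites <- seq_len(panel$map$n_loci)
  set.seed(7)
  parent <- founder_ind(9, 30, panel)
  dhs <- replicate(3000, make_dh(parent, panel$map), simplify = FALSE)
  expect_equal(heterozygosity(dhs[1:50], sites, panel), 0)
  bv <- tbv(dhs, trait, panel)
  expect_lt(abs(mean(bv) - tbv(parent, trait, panel)),
            3 * sd(bv) / sqrt(length(bv)))
  # DH of an inbred is a clone of the inbred
  inb <- founder_ind(12, 12, panel)
  clone <- make_dh(inb, panel$map)
  expect_identical(prebreedsim:::dosage_at(list(clone), sites, panel),
                   prebreedsim:::dosage_at(list(inb), sites, panel))
})

test_that("random mating produces the expected seed count without selfing", {
  panel <- toy_panel()
  set.seed(8)
  plants <- lapply(1:10, function(i) founder_ind(2 * i - 1, 2 * i, panel,
                                                 id = i))
  seeds <- random_mate(plants, 10, panel$map)
  expect_length(seeds, 100)
  expect_true(all(vapply(seeds, function(s) s$mother != s$father, logical(1))))
  expect_error(random_mate(plants[1], 5, panel$map), "two plants")

  # offspring allele frequencies track the parental pool
  loci <- panel$map$candidate_marker_index[1:40]
  p_par <- colMeans(prebreedsim:::dosage_at(plants, loci, panel)) / 2
  p_off <- colMeans(prebreedsim:::dosage_at(seeds, loci, panel)) / 2
  se <- sqrt(pmax(p_par * (1 - p_par), 1e-9) / (2 * length(seeds)))
  expect_true(all(abs(p_off - p_par) <= 3 * se + 0.05))
})
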