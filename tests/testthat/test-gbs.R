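test_that("marker panels avoid QTL and spread proportionally to map length", {
  panel <- tiny_panel()
  map <- panel$map
  set.seed(10)
  mk <- select_marker_panel(map, 500)
  expect_length(intersect(mk, map$qtl_index), 0)
  counts <- tabulate(map$chrom[mk], map$n_chrom)
  expected <- map$chrom_length_cm / sum(map$chrom_length_cm) * 500
  expect_true(all(abs(counts - expected) <= 0.1 * expected + 1))

  all_cand <- select_marker_panel(map, length(map$candidate_marker_index))
  expect_identical(all_cand, map$candidate_marker_index)
  expect_error(select_marker_panel(map, map$n_loci + 1), "candidate")
})

test_that("dosages converge to the true genotype as coverage grows", {
  panel <- toy_panel()
  set.seed(11)
  inds <- lapply(1:30, function(i) founder_ind(sample(80, 1), sample(80, 1),
                                               panel))
  mk <- panel$map$candidate_marker_index
  truth <- prebreedsim:::dosage_at(inds, mk, panel)
  deep <- gbs_platform(length(mk), coverage = 400, error_rate = 0)
  g <- gbs_genotype(inds, deep, mk, panel)
  expect_lt(max(abs(g$dosage - truth)), 1e-6)
  expect_true(all(g$dosage >= 0 & g$dosage <= 2))
})

test_that("a 1x platform leaves about exp(-1) of entries unread", {
  panel <- toy_panel()
  set.seed(12)
  inds <- lapply(1:60, function(i) founder_ind(sample(80, 1), sample(80, 1),
                                               panel))
  mk <- panel$map$candidate_marker_index
  g <- gbs_genotype(inds, gbs_platform(length(mk), 1), mk, panel)
  n <- length(g$missing)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(mean(g$missing) - exp(-1)), 3 * se)
  # missing entries are flagged and mean-imputed, never silently zero
  pm <- matrix(g$freq, nrow(g$dosage), ncol(g$dosage), byrow = TRUE)
  expect_equal(g$dosage[g$missing], (2 * pm)[g$missing])
})

test_that("with error-free concordant reads dosages sit on the correct side of 1", {
  panel <- toy_panel()
  set.seed(13)
  inds <- lapply(1:20, function(i) {
    h <- sample(80, 1)
    founder_ind(h, h, panel)  # fully homozygous
  })
  mk <- panel$map$candidate_marker_index
  truth <- prebreedsim:::dosage_at(inds, mk, panel)
  g <- gbs_genotype(inds, gbs_platform(length(mk), 2, error_rate = 0), mk, panel)
  seen <- !g$missing
  poly <- matrix(g$freq > 0 & g$freq < 1, nrow(truth), ncol(truth),
                 byrow = TRUE)
  sel0 <- seen & poly & truth == 0
  sel2 <- seen & poly & truth == 2
  expect_true(all(g$dosage[sel0] < 1))
  expect_true(all(g$dosage[sel2] > 1))
})

test_that("dosage error is non-increasing in coverage", {
  panel <- toy_panel()
  set.seed(14)
  inds <- lapply(1:80, function(i) founder_ind(sample(80, 1), sample(80, 1),
                                               panel))
  mk <- panel$map$candidate_marker_index
  truth <- prebreedsim:::dosage_at(inds, mk, panel)
  mse <- vapply(c(0.5, 1, 2, 5, 10), function(cov) {
    g <- gbs_genotype(inds, gbs_platform(length(mk), cov), mk, panel)
    mean((g$dosage - truth)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 0.002))
  expect_error(gbs_genotype(list(), gbs_platform(10, 1), mk[1:10], panel),
               "empty")
})
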