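make_records <- function(n, effects = list(), sd = 1, seed = 1) {
  # synthetic stage-record-like table with 3 design factors
  set.seed(seed)
  d <- data.frame(
    platform = sample(c("A", "B"), n, replace = TRUE),
    h2 = sample(c(0.25, 0.5), n, replace = TRUE),
    n_syn = sample(c(0, 20, 40, 60), n, replace = TRUE),
    stage = "S"
  )
  y <- rnorm(n, 0, sd)
  for (f in names(effects)) y <- y + effects[[f]] * as.numeric(factor(d[[f]]))
  d$merit <- y
  d
}

test_that("marginal effects separate a planted 1-SD factor at p < 0.01", {
  d <- make_records(200, effects = list(platform = 1), seed = 51)
  me <- marginal_effects(d, "merit", factors = c("platform", "h2"),
                         alpha = 0.01)
  pl <- me[me$factor == "platform", ]
  expect_false(any(mapply(grepl, strsplit(pl$letters[1], "")[[1]],
                          pl$letters[2])))
  h2 <- me[me$factor == "h2", ]
  expect_true(any(mapply(grepl, strsplit(h2$letters[1], "")[[1]],
                         h2$letters[2])))
  expect_true(all(me$q2.5 <= me$mean & me$mean <= me$q97.5))
})

test_that("identical groups share a letter", {
  d <- make_records(100, seed = 52)
  d2 <- rbind(d, d)
  d2$platform <- rep(c("A", "B"), each = 100)
  d2$merit <- rep(d$merit, 2)  # both levels carry the same records
  me <- marginal_effects(d2, "merit", factors = "platform")
  expect_equal(me$letters[1], me$letters[2])
  expect_equal(me$mean[1], me$mean[2])
})

test_that("a pure-noise response yields a single-leaf tree", {
  d <- make_records(300, seed = 53)
  tr <- build_tree(d, "merit", factors = c("platform", "h2", "n_syn"),
                   alpha = 0.01, min_leaf = 20, n_perm = 400, seed = 5)
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$n, 300)
})

test_that("a dominant factor is chosen at the root and leaves conserve the mean", {
  d <- make_records(300, effects = list(platform = 2, n_syn = 0.3), seed = 54)
  tr <- build_tree(d, "merit", factors = c("platform", "h2", "n_syn"),
                   alpha = 0.01, min_leaf = 20, n_perm = 400, seed = 5)
  expect_equal(tr$root$type, "node")
  expect_equal(tr$root$factor, "platform")
  leaf_sum <- function(node) {
    if (node$type == "leaf") c(node$mean * node$n, node$n)
    else leaf_sum(node$left) + leaf_sum(node$right)
  }
  s <- leaf_sum(tr$root)
  expect_equal(s[1] / s[2], mean(d$merit))
  nc <- tree_node_count(tr)
  expect_equal(nc$leaves, nc$internal + 1)
})

test_that("trees are monotone in alpha", {
  d <- make_records(240, effects = list(platform = 0.6, n_syn = 0.2), seed = 55)
  leaves <- function(alpha, min_leaf) {
    tree_node_count(build_tree(d, "merit",
                               factors = c("platform", "h2", "n_syn"),
                               alpha = alpha, min_leaf = min_leaf,
                               n_perm = 300, seed = 5))$leaves
  }
  expect_equal(leaves(1e-12, 20), 1)
  expect_gte(leaves(0.999, 5), leaves(0.01, 20))
})

test_that("tree JSON round-trips and renders deterministically", {
  d <- make_records(300, effects = list(platform = 1.5), seed = 56)
  tr <- build_tree(d, "merit", factors = c("platform", "h2"),
                   alpha = 0.01, min_leaf = 20, n_perm = 300, seed = 5)
  js <- tree_to_json(tr)
  back <- tree_from_json(js)
  expect_equal(render_tree(back), render_tree(tr))
  expect_equal(tree_to_json(back), js)
})

test_that("the alpha = 0.01 split gate controls its false-split rate", {
  false_splits <- 0L
  for (i in 1:200) {
    d <- make_records(64, seed = 1000 + i)
    tr <- build_tree(d, "merit", factors = c("platform", "h2", "n_syn"),
                     alpha = 0.01, min_leaf = 10, n_perm = 300,
                     seed = 2000 + i)
    if (tr$root$type == "node") false_splits <- false_splits + 1L
  }
  expect_lte(false_splits / 200, 0.05)
})
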