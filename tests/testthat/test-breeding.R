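test_that("the full factorial grid enumerates 3,456 unique scenarios", {
  g <- scenario_grid()
  expect_equal(nrow(g), 3456)
  expect_equal(nrow(g), 3 * 2 * 2 * 2 * 2 * 3 * 2 * 3 * 4)
  expect_false(anyDuplicated(g$scenario_id) > 0)
  expect_false(anyDuplicated(g[, -1]) > 0)
  expect_setequal(unique(g$approach),
                  c("Landrace", "LandraceDH", "LandraceElite"))
})

test_that("discovery selects 10 units from 10 distinct accessions", {
  w <- tiny_world()
  for (app in c("Landrace", "LandraceDH", "LandraceElite")) {
    scn <- scenario(app, 1000, 0.3, 0.5, "GBS10x@10K", 1, 40, 10, 0)
    disc <- run_discovery(w, scn, seed = 61)
    expect_length(disc$units, 10)
    origin <- vapply(disc$units, function(u) {
      if (app == "Landrace") u$id else u$mother
    }, integer(1))
    expect_length(unique(origin), 10)
    expect_equal(disc$records$stage, c("T", "A", "S"))
    if (app == "LandraceDH") {
      sites <- seq_len(w$map$n_loci)
      expect_equal(heterozygosity(disc$units, sites, w$panel), 0)
    }
    if (app == "LandraceElite") {
      # testcross units carry half the elite genome
      expect_gt(disc$records$kinship_with_elite[3], 0.15)
      expect_gt(disc$records$merit[3], 0.3)
    }
  }
})

test_that("training population size follows seeds_per_landrace", {
  w <- tiny_world()
  scn <- scenario("Landrace", 1000, 0.3, 0.5, "GBS10x@10K", 3, 40, 10, 0)
  disc <- run_discovery(w, scn, seed = 62)
  # 60 accessions x 3 seeds: the ridge intercept was trained on 180 records
  expect_length(disc$eq$centers, disc$platform$n_markers)
  expect_equal(disc$eq$training_id, "discovery")
  expect_equal(length(w$accessions) * 3L, 180L)
})

test_that("improvement respects the equation lag and is deterministic", {
  w <- tiny_world()
  scn0 <- scenario("Landrace", 1000, 0.3, 0.5, "GBS10x@10K", 1, 40, 10, 0)
  scn60 <- scenario("Landrace", 1000, 0.3, 0.5, "GBS10x@10K", 1, 40, 10, 60)
  disc <- run_discovery(w, scn0, seed = 63)
  imp0 <- run_improvement(w, scn0, disc, seed = 64)
  imp60 <- run_improvement(w, scn60, disc, seed = 64)
  expect_equal(imp0$stage, c("C1", "C2", "C3", "C4"))
  # phenotypes collected in C1 cannot influence C1 selection
  expect_equal(imp60[imp60$stage == "C1", ], imp0[imp0$stage == "C1", ])
  # rerun reproduces exactly
  imp0b <- run_improvement(w, scn0, disc, seed = 64)
  expect_equal(imp0, imp0b)
})

test_that("run_grid shares worlds, stacks 7 stages, and reruns identically", {
  g <- scenario_grid()
  sub <- g[g$approach == "Landrace" & g$Ne == 1000 & g$F_within == 0.3 &
             g$h2 == 0.5 & g$platform == "GBS10x@10K" &
             g$seeds_per_landrace == 1 & g$n_selected_landraces == 40 &
             g$tested_seeds_per_landrace == 10 &
             g$n_synthetic_phenotypes %in% c(0, 20), ]
  expect_equal(nrow(sub), 2)
  cfg <- default_config(scale = 0.015)  # 45 accessions: enough to select 40
  r1 <- run_grid(sub, n_replicates = 1, master_seed = 77, config = cfg)
  expect_equal(nrow(r1), 2 * 1 * 7)
  expect_equal(sort(unique(r1$stage)), sort(c("T", "A", "S", paste0("C", 1:4))))
  expect_equal(attr(r1, "provenance")$master_seed, 77)
  r2 <- run_grid(sub, n_replicates = 1, master_seed = 77, config = cfg)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_error(run_grid(rbind(sub, sub[1, ]), 1, 77, cfg), "duplicate")
})

test_that("mismatched worlds and scenarios are rejected", {
  w <- tiny_world()
  scn <- scenario("Landrace", 100000, 0.3, 0.5, "GBS10x@10K", 1, 40, 10, 0)
  expect_error(run_scenario(w, scn, seed = 1), "does not match")
  scn2 <- scenario("Landrace", 1000, 0.3, 0.5, "GBS10x@10K", 1, 80, 10, 0)
  expect_error(run_discovery(w, scn2, seed = 1), "more landraces")
})
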