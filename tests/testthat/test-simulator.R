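test_that("an empty landscape stays empty but the clock advances", {
  cfg <- sim_config(grid_spec(40, 40), years = 3)
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(sim$record$year, 3)
  expect_equal(sim$record$adult_count, 0)
  expect_equal(sim$record$n1_total + sim$record$n2_total, 0)
  expect_length(sim$state$browsing, 3)
})

test_that("a zero-year run returns the initial summaries", {
  cfg <- sim_config(grid_spec(40, 40), years = 0)
  ad <- adult_population(1:5, runif(5, 0, 40), runif(5, 0, 40),
                         c(3, 5, 8, 12, 19))
  sim <- run_simulation(cfg, ad, seed = 2)
  expect_equal(sim$record$adult_count, 5)
  expect_equal(sim$record$adult_ba_m2, basal_area(ad))
  expect_equal(sim$record$year, 0)
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- sim_config(grid_spec(60, 60), years = 5, browsing_mu = 0.3,
                    substrate_mu = 0.8)
  ad <- build_core_scenario(grid_spec(60, 60), 500, core_ha = 0.09,
                            seed = 3)
  s1 <- run_simulation(cfg, ad, seed = 99)
  s2 <- run_simulation(cfg, ad, seed = 99)
  expect_identical(s1$record, s2$record)
  expect_identical(s1$state$adults, s2$state$adults)
  expect_identical(s1$state$juveniles$n1, s2$state$juveniles$n1)
  expect_identical(s1$state$browsing, s2$state$browsing)
})

test_that("without recruitment the adult count decays geometrically", {
  g <- grid_spec(300, 300)
  cfg <- sim_config(g, years = 30, substrate_mu = 0, substrate_sd = 0)
  set.seed(17)
  n0 <- 600
  ad <- adult_population(seq_len(n0), runif(n0, 0, 300),
                         runif(n0, 0, 300), runif(n0, 3, 20))
  sim <- run_simulation(cfg, ad, seed = 18, keep_yearly = FALSE)
  expected <- n0 * 0.975^30  # 0.468 N0
  expect_lt(abs(sim$record$adult_count - expected),
            4 * sqrt(n0 * 0.468 * 0.532) + 5)
  expect_equal(sim$record$n1_total, 0)
})

test_that("core scenario builders place the right number of trees in the block", {
  g <- grid_spec(2000, 2000)
  ad250 <- build_core_scenario(g, 250, seed = 4)
  ad500 <- build_core_scenario(g, 500, seed = 5)
  expect_equal(nrow(ad250), 4000)  # 250 / ha x 16 ha
  expect_equal(nrow(ad500), 8000)
  # central 400 x 400 m block
  expect_true(all(ad500$x >= 800 & ad500$x <= 1200 &
                  ad500$y >= 800 & ad500$y <= 1200))
  expect_true(all(ad500$height >= 3 & ad500$height <= 20))
  expect_lt(abs(mean(ad500$height) - 11.5), 4 * (17 / sqrt(12)) / sqrt(8000))
})

test_that("patch scenario builds ten disjoint islets holding 8000 adults", {
  g <- grid_spec(2000, 2000)
  ad <- build_patch_scenario(g, seed = 6)
  expect_equal(nrow(ad), 8000)
  pt <- attr(ad, "patches")
  expect_equal(nrow(pt$corners), 10)
  expect_equal(pt$side, sqrt(1000), tolerance = 1e-9)  # 0.1 ha square
  # patches pairwise disjoint
  for (i in 1:9) for (j in (i + 1):10) {
    expect_true(abs(pt$corners[i, 1] - pt$corners[j, 1]) >= pt$side ||
                abs(pt$corners[i, 2] - pt$corners[j, 2]) >= pt$side)
  }
  # all adults inside the central 1000 x 1000 m block, 800 per patch
  expect_true(all(ad$x >= 500 & ad$x <= 1500 & ad$y >= 500 & ad$y <= 1500))
  in_patch <- sapply(seq_len(10), function(p)
    sum(ad$x >= pt$corners[p, 1] & ad$x <= pt$corners[p, 1] + pt$side &
        ad$y >= pt$corners[p, 2] & ad$y <= pt$corners[p, 2] + pt$side))
  expect_equal(in_patch, rep(800, 10))
})

test_that("scenario plans enumerate the full factorial with derived seeds", {
  plan <- scenario_plan()
  expect_equal(nrow(unique(plan[, c("mu_b", "mu_s")])), 121)
  expect_equal(nrow(plan), 12100)
  small <- scenario_plan(c(0, 1), c(0, 1), reps = 1)
  expect_equal(nrow(small), 4)
  expect_false(any(duplicated(plan$seed)))
  expect_true(all(plan$seed >= 0 & plan$seed < 2^31))
  # same master seed reproduces the plan; replicate defines the adult map
  expect_identical(plan, scenario_plan())
  expect_equal(length(unique(plan$adult_seed)), 100)
})

test_that("the grid runner is deterministic and browsing suppresses regeneration", {
  g <- grid_spec(120, 120)
  cfg <- sim_config(g, years = 15)
  plan <- scenario_plan(browse_means = c(0, 1), substrate_means = 0.8,
                        reps = 3, density = 500, master_seed = 5)
  rec <- run_scenario_grid(cfg, plan, core_ha = 0.36)
  rec2 <- run_scenario_grid(cfg, plan, core_ha = 0.36)
  expect_identical(rec, rec2)
  agg <- tapply(rec$n1_total + rec$n2_total, rec$mu_b, mean)
  # common random numbers: unbrowsed landscapes regenerate more
  expect_gt(agg[["0"]], agg[["1"]])
  expect_true(all(rec$n2_total >= 0 & rec$adult_ba_m2 >= 0))
})

test_that("carbon stock counts only trees above the reference height", {
  expect_equal(carbon_stock(adult_population()), 0)
  n <- 5800
  tall <- adult_population(seq_len(n), runif(n), runif(n), rep(9, n))
  expect_equal(carbon_stock(tall), 60.32)  # 5800 x 10.4 kg / 1000
  mixed <- adult_population(1:3, 1:3, 1:3, c(8.4, 8.5, 8.6))
  expect_equal(carbon_stock(mixed), 10.4 / 1000)  # only the 8.6-m tree
})
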