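test_that("dispersal fit recovers a known kernel, STR and favorabilities", {
  set.seed(31)
  tb <- truth_bundle()
  ad <- gen_adult_map(25, extent = c(0, 80, 0, 80), pattern = "clustered",
                      seed = 32)
  sv <- gen_quadrat_survey(ad, tb, 800, seed = 33)
  fit <- fit_dispersal(sv)
  expect_false(fit$boundary)
  expect_equal(fit$family, "lognormal")  # AIC prefers the generating family
  expect_equal(fit$mode_m, 0.67, tolerance = 0.35)
  expect_equal(fit$str_total, 1046, tolerance = 0.25)
  expect_equal(unname(fit$favorability["grass"]), 1)  # max-normalized
  expect_equal(unname(fit$favorability["moor"]), 0.15, tolerance = 0.12)
  expect_lt(fit$aic["lognormal"], fit$aic["negexp"])
})

test_that("dispersal fit is equivariant to translation and class relabeling", {
  set.seed(41)
  tb <- truth_bundle()
  ad <- gen_adult_map(15, extent = c(0, 50, 0, 50), seed = 42)
  sv <- gen_quadrat_survey(ad, tb, 300, seed = 43)
  set.seed(44); f1 <- fit_dispersal(sv)
  # translate all coordinates
  sv2 <- sv
  sv2$quadrats$x <- sv$quadrats$x + 137
  sv2$adults$x <- sv$adults$x + 137
  set.seed(44); f2 <- fit_dispersal(sv2)
  expect_equal(f1$mode_m, f2$mode_m, tolerance = 1e-6)
  expect_equal(f1$str_total, f2$str_total, tolerance = 1e-6)
  # relabel / reorder cover classes
  sv3 <- sv
  sv3$cover <- sv$cover[, c("moor", "grass")]
  set.seed(44); f3 <- fit_dispersal(sv3)
  expect_equal(unname(f3$favorability[c("grass", "moor")]),
               unname(f1$favorability[c("grass", "moor")]),
               tolerance = 1e-3)
})

test_that("an all-zero survey raises the boundary flag", {
  tb0 <- truth_bundle(production = recruit_production(str_total = 1e-9,
                                                      str_multiplier = 1))
  ad <- gen_adult_map(5, extent = c(0, 30, 0, 30), seed = 51)
  sv <- gen_quadrat_survey(ad, tb0, 50, seed = 52)
  expect_true(all(sv$quadrats$count == 0))
  fit <- fit_dispersal(sv)
  expect_true(fit$boundary)
  expect_equal(fit$str_total, 0)
})

test_that("stage-rate fit recovers the generating rates and browsing effect", {
  set.seed(61)
  tb <- truth_bundle(stages = stage_rates(s1 = 0.9, g1 = 0.01))
  ser <- gen_transect_series(tb, seed = 62)
  fit <- fit_stage_rates(ser, n_boot = 25)
  expect_true(fit$delta_identifiable)
  expect_equal(fit$s1, 0.9, tolerance = 0.05)
  expect_equal(fit$g1, 0.01, tolerance = 0.8)
  expect_equal(fit$delta_max, 0.48, tolerance = 0.15)
  expect_true(fit$ci["2.5%", "s1"] <= 0.9 && fit$ci["97.5%", "s1"] >= 0.9)
  expect_gt(fit$plot_sd, 0)
})

test_that("constant browsing makes the deer effect unidentifiable", {
  set.seed(71)
  tb <- truth_bundle()
  ser <- gen_transect_series(tb, browse_means = rep(0.4, 6), seed = 72)
  ser$browsed <- 0.4  # exactly constant
  fit <- fit_stage_rates(ser, n_boot = 0)
  expect_false(fit$delta_identifiable)
  expect_true(is.na(fit$delta_max))
})

test_that("constant growth reduces the size-structure fit to the exponential-rate MLE", {
  set.seed(81)
  g0 <- 1.2  # cm / y
  m0 <- 0.024
  d <- rexp(3000, m0 / g0)
  d <- d[d < 400][1:2000]
  # wide normalization range: the truncation correction is negligible
  # and the MLE reduces to the exponential-rate estimator g / mean(d)
  fit <- fit_adult_mortality(d, growth_fn = function(x) rep(g0, length(x)),
                             range = c(0, 2000))
  expect_equal(fit$m, g0 / mean(d), tolerance = 1e-3)
  expect_true(fit$ci[1] <= m0 && fit$ci[2] >= m0)
  expect_error(fit_adult_mortality(rep(5, 30)), "degenerate")
  expect_error(fit_adult_mortality(d[1:10]), "at least 20")
})

test_that("diameter samples follow the equilibrium size distribution", {
  tb <- truth_bundle()
  d <- gen_dbh_sample(tb, n = 4000, seed = 91)
  expect_length(d, 4000)
  # independent CDF oracle: numeric integral of phi(d) ~ exp(-m T(d)) / g(d)
  params <- tb$adult
  gfun <- function(dd) {
    h <- height_from_dbh(dd, params)
    height_growth_rate(pmax(h, 3), params) * params$hd_a * params$hd_b *
      (h - 1.3)^(params$hd_b - 1)
  }
  lo <- dbh_from_height(3, params); hi <- dbh_from_height(28, params)
  grid <- seq(lo, hi, length.out = 4000)
  Tg <- cumsum(c(0, (1 / gfun(grid[-1]) + 1 / gfun(grid[-4000])) / 2 *
                   diff(grid)))
  cdf <- (1 - exp(-params$mortality_m * Tg))
  cdf <- cdf / max(cdf)
  ks <- suppressWarnings(
    ks.test(d, function(q) approx(grid, cdf, xout = q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
  # the fitter recovers the generating mortality
  fit <- fit_adult_mortality(d, range = c(lo, hi))
  expect_equal(fit$m, 0.025, tolerance = 0.1)
})

test_that("synthetic generators are seed-deterministic and correctly scaled", {
  expect_equal(nrow(gen_adult_map(0)), 0)
  ad <- gen_adult_map(8000, extent = c(0, 400, 0, 400), seed = 1)
  expect_equal(nrow(ad), 8000)  # 500 / ha on 16 ha
  expect_true(all(ad$x >= 0 & ad$x <= 400 & ad$y >= 0 & ad$y <= 400))
  expect_identical(ad, gen_adult_map(8000, extent = c(0, 400, 0, 400),
                                     seed = 1))
  tb <- truth_bundle()
  sv1 <- gen_quadrat_survey(ad[1:20, ], tb, 100, seed = 2)
  sv2 <- gen_quadrat_survey(ad[1:20, ], tb, 100, seed = 2)
  expect_identical(sv1$quadrats, sv2$quadrats)
  expect_equal(sv1$area_m2, 0.25)
  # empirical mean count tracks the mean Poisson intensity
  sv3 <- gen_quadrat_survey(ad[1:50, ], tb, 4000, seed = 3)
  lam <- attr(sv3, "lambda")
  expect_lt(abs(mean(sv3$quadrats$count) - mean(lam)),
            4 * sqrt(sum(lam)) / 4000)
  ser1 <- gen_transect_series(tb, seed = 4)
  expect_identical(ser1, gen_transect_series(tb, seed = 4))
  expect_equal(dim(ser1), c(6 * 10 * 8, 6))
  d1 <- gen_dbh_sample(tb, seed = 5)
  expect_length(d1, 40)
  expect_identical(d1, gen_dbh_sample(tb, seed = 5))
})

test_that("transect series decline at the effective survival rate without recruitment", {
  tb <- truth_bundle(recruit_rate = 1e-9, plot_sd = 0, year_sd = 0)
  ser <- gen_transect_series(tb, n_transects = 2, n_plots = 40,
                             n_years = 2, browse_means = c(0, 0),
                             init_n1 = 500, init_n2 = 0, seed = 6)
  y1 <- ser$n1[ser$year == 1]
  y2 <- ser$n1[ser$year == 2]
  # browsing drawn near zero: survival ~ s1 (advancement negligible)
  ratio <- sum(y2) / sum(y1)
  m_eff <- mean(1 - 0.48 * ser$browsed[ser$year == 1])
  expect_equal(ratio, 0.95 * m_eff * (1 - 0.0065 * m_eff),
               tolerance = 0.02)
})
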