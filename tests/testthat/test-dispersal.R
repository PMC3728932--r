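test_that("kernel density peaks at the requested mode and integrates to one", {
  for (mode in c(0.3, 0.67, 2)) {
    for (lsd in c(0.5, 1, 1.5)) {
      k <- dispersal_kernel(mode, lsd, truncation_radius_m = 1e9)
      peak <- optimize(function(r) kernel_density(r, k),
                       c(1e-4, 30), maximum = TRUE)
      expect_equal(peak$maximum, mode, tolerance = 1e-3)
      mass <- integrate(function(r) kernel_density(r, k) * 2 * pi * r,
                        0, Inf, rel.tol = 1e-9)$value
      expect_equal(mass, 1, tolerance = 1e-6)
    }
  }
})

test_that("default kernel is negligible at 100 m and zero outside its domain", {
  k <- dispersal_kernel()
  # direct evaluation of (0.67/100)^2 * exp(.) with mu_ln = log(0.67) + 2
  ratio <- kernel_density(100, k) / kernel_density(0.67, k)
  expect_equal(ratio, 3.6228e-06, tolerance = 1e-4)
  expect_equal(kernel_density(0, k), 0)      # limit at the origin
  expect_equal(kernel_density(100.01, k), 0) # beyond truncation
  expect_error(kernel_density(-1, k), "non-negative")
})

test_that("expected recruitment field is zero without adults or favorability", {
  s <- unit_substrate(30)
  k <- dispersal_kernel()
  p <- recruit_production()
  expect_equal(expected_recruitment_field(adult_population(), s, k, p),
               matrix(0, 30, 30))
  s0 <- unit_substrate(30, value = 0)
  ad <- adult_population(1, 15.2, 15.7, 10)
  expect_equal(expected_recruitment_field(ad, s0, k, p),
               matrix(0, 30, 30))
})

test_that("one adult sheds its annual production onto the landscape", {
  g <- grid_spec(240, 240)
  s <- draw_substrate_field(g, 1, 0)
  k <- dispersal_kernel()
  p <- recruit_production()  # 1046 * 1.10 / 27 = 42.61 recruits / y
  ad <- adult_population(1, 120.3, 120.2, 10)
  lam <- expected_recruitment_field(ad, s, k, p)
  expect_true(all(lam >= 0))
  # landscape total ~ annual production x in-range kernel mass
  expect_equal(sum(lam), p$annual * kernel_mass(k), tolerance = 5e-3)
  expect_equal(p$annual, 1046 * 1.10 / 27)
  # linearity: duplicating the adult doubles the field exactly
  ad2 <- adult_population(1:2, rep(120.3, 2), rep(120.2, 2), rep(10, 2))
  expect_equal(expected_recruitment_field(ad2, s, k, p), 2 * lam)
})

test_that("FFT stamp engine agrees with the exact field", {
  g <- grid_spec(240, 240)
  s <- draw_substrate_field(g, 1, 0)
  k <- dispersal_kernel()
  p <- recruit_production()
  set.seed(5)
  ad <- adult_population(1:4, runif(4, 100, 140), runif(4, 100, 140),
                         rep(10, 4))
  exact <- expected_recruitment_field(ad, s, k, p)
  K <- kernel_stamp(k)
  expect_equal(sum(K), kernel_mass(k), tolerance = 1e-3)
  fft_field <- birchspread:::conv2_stamp(birchspread:::bin_adults(ad, g),
                                         K) * p$annual
  expect_equal(sum(fft_field), sum(exact), tolerance = 5e-3)
  # fields agree cell-wise away from every source cell (the stamp
  # averages within-cell source position, so near-field cells differ)
  cc <- cell_centers(g)
  far <- matrix(TRUE, 240, 240)
  for (a in seq_len(nrow(ad))) {
    d2 <- outer((cc$y - ad$y[a])^2, (cc$x - ad$x[a])^2, "+")
    far <- far & d2 > 6^2
  }
  expect_lt(max(abs(fft_field[far] - exact[far])), 0.05 * max(exact))
})

test_that("recruitment draw respects the per-cell cap", {
  jg <- one_cell_grid(n1 = 10)
  lam <- matrix(0, 5, 5)
  expect_identical(recruit(jg, lam, seed = 1), jg)  # nothing to add
  lam[3, 3] <- 1e4  # Poisson draw far above the cap
  out <- recruit(jg, lam, seed = 1)
  expect_equal(out$n_new[3, 3], 40L)  # 50 - 10 occupied
  expect_equal(out$n_new[3, 3] + out$n1[3, 3] + out$n2[3, 3], 50L)
  expect_error(recruit(jg, lam - 1), "non-negative")
})

test_that("far below the cap, mean recruits equal the Poisson mean", {
  g <- grid_spec(100, 100)
  jg <- juvenile_grid(g)
  lam <- matrix(5, 100, 100)  # 1e4 independent cells at lambda = 5
  out <- recruit(jg, lam, seed = 42)
  expect_lt(abs(mean(out$n_new) - 5), 4 * sqrt(5 / 1e4))
})
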