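test_that("predictor standardization is exact and invertible", {
  set.seed(1)
  X <- cbind(a = rnorm(50, 5, 2), b = runif(50), c = rpois(50, 3))
  Xs <- standardize_predictors(X)
  expect_equal(unname(colMeans(Xs)), rep(0, 3))
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 3))
  # idempotent up to numerics
  expect_equal(unclass(standardize_predictors(Xs))[, ], Xs[, ],
               tolerance = 1e-12)
  # round trip
  back <- sweep(sweep(Xs, 2, attr(Xs, "scale"), "*"), 2,
                attr(Xs, "center"), "+")
  expect_equal(back[, ], X[, ], tolerance = 1e-12)
  expect_error(standardize_predictors(cbind(X, d = rep(2, 50))),
               "constant")
})

test_that("Poisson IRLS agrees with brute-force likelihood maximization", {
  set.seed(2)
  n <- 200
  x <- runif(n, -1, 1)
  y <- rpois(n, exp(1 + 0.5 * x))
  fit <- fit_poisson_overdispersed(y, cbind(x = x))
  Xd <- cbind(1, x)
  nll <- function(b) sum(exp(Xd %*% b)) - sum(y * (Xd %*% b))
  grad <- function(b) as.vector(t(Xd) %*% (exp(Xd %*% b) - y))
  op <- optim(c(0, 0), nll, grad, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-15))
  expect_equal(unname(coef(fit)), op$par, tolerance = 1e-6)
})

test_that("dispersion is near one for truly Poisson data", {
  set.seed(3)
  disp <- replicate(40, {
    x <- runif(200)
    y <- rpois(200, exp(0.5 + x))
    fit_poisson_overdispersed(y, cbind(x = x))$dispersion
  })
  expect_lt(abs(mean(disp) - 1), 3 * sd(disp) / sqrt(40))
})

test_that("Wald CIs achieve near-nominal coverage in both GLM variants", {
  set.seed(4)
  n_rep <- 150
  cover_p <- cover_g <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- runif(250, -1, 1)
    yp <- rpois(250, exp(1 + 0.5 * x))
    fp <- fit_poisson_overdispersed(yp, cbind(x = x))$effects
    cover_p[r] <- fp$ci_lo[2] <= 0.5 && fp$ci_hi[2] >= 0.5
    yg <- exp(0.3 + 0.8 * x + rnorm(250, 0, 0.4))
    fg <- fit_gaussian_log(yg, cbind(x = x))$effects
    cover_g[r] <- fg$ci_lo[2] <= 0.8 && fg$ci_hi[2] >= 0.8
  }
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n_rep, 0.95)
  expect_gte(sum(cover_p), bounds[1])
  expect_lte(sum(cover_p), bounds[2])
  expect_gte(sum(cover_g), bounds[1])
  expect_lte(sum(cover_g), bounds[2])
})

test_that("degenerate responses are handled as specified", {
  y <- rep(7L, 30)
  fit <- fit_poisson_overdispersed(y, matrix(numeric(0), 30, 0))
  expect_equal(fit$deviance_explained, 0)
  expect_equal(nrow(fit$effects), 1)  # intercept only
  expect_error(fit_poisson_overdispersed(c(1.5, 2), cbind(x = 1:2)),
               "integer")
  expect_error(fit_gaussian_log(c(1, 0, 2), cbind(x = 1:3)), "positive")
  # exact log-linear response is fitted perfectly
  x <- seq(-1, 1, length.out = 20)
  # a perfect fit makes summary.lm warn about unreliable SEs
  fitg <- suppressWarnings(fit_gaussian_log(exp(2 + 3 * x), cbind(x = x)))
  expect_equal(unname(coef(fitg)), c(2, 3), tolerance = 1e-10)
  expect_equal(fitg$deviance_explained, 1, tolerance = 1e-10)
})

test_that("validation of perfect predictions yields the identity line", {
  obs <- c(5, 8, 12, 3, 7, 0, 22, 15)
  rep_v <- validate(obs, obs)
  expect_equal(rep_v$slope, 1, tolerance = 1e-8)
  expect_equal(rep_v$intercept, 0, tolerance = 1e-6)
  expect_true(rep_v$covers_unbiased)
  expect_equal(rep_v$deviance_explained, 1, tolerance = 1e-8)
})

test_that("multiplier calibration recovers truth on an unbiased harness", {
  # noise-free observations; median predictions from Poisson simulation.
  # the harness responds to s1 through five years of survival.
  lam_base <- seq(10, 300, length.out = 150)
  harness <- function(str_mult, s1_mult) {
    set.seed(11)
    lam <- lam_base * str_mult * s1_mult^5
    preds <- replicate(300, rpois(length(lam), lam))
    validate(apply(preds, 1, median), lam_base)
  }
  cal <- calibrate_multipliers(harness)
  expect_equal(cal$str_mult, 1.0)
  expect_equal(cal$s1_mult, 1.0)
  expect_equal(nrow(cal$surface), 49)  # 7 x 7 grid
})
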