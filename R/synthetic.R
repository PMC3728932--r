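#' Ground-truth parameter bundle for synthetic data
#'
#' Collects the full generating parameter set used by the synthetic
#' data generators, so that every generated dataset carries its truth
#' alongside for parameter-recovery testing.
#'
#' @param kernel A \code{dispersal_kernel}.
#' @param production A \code{recruit_production} (its multiplier is 1
#'   by default here: truth is unbiased unless a bias is planted).
#' @param favorability Named vector of ground-cover favorabilities in
#'   (0, 1], maximum exactly 1.
#' @param stages A \code{stage_rates}.
#' @param browsing_effect A \code{browsing_effect}.
#' @param adult An \code{adult_params}.
#' @param recruit_rate Expected new recruits per transect plot per year
#'   (default 5).
#' @param plot_sd,year_sd Logit-scale SDs of plot and year random
#'   effects on tier-1 survival in the transect generator
#'   (defaults 0.15).
#' @return Object of class \code{"truth_bundle"}.
#' @export
truth_bundle <- function(kernel = dispersal_kernel(),
                         production = recruit_production(str_multiplier = 1),
                         favorability = c(grass = 1, moor = 0.15),
                         stages = stage_rates(),
                         browsing_effect = birchspread::browsing_effect(),
                         adult = adult_params(),
                         recruit_rate = 5,
                         plot_sd = 0.15, year_sd = 0.15) {
  stopifnot(abs(max(favorability) - 1) < 1e-12, all(favorability > 0))
  structure(list(kernel = kernel, production = production,
                 favorability = favorability, stages = stages,
                 browsing_effect = browsing_effect, adult = adult,
                 recruit_rate = recruit_rate,
                 plot_sd = plot_sd, year_sd = year_sd),
            class = "truth_bundle")
}

#' Generate an adult map
#'
#' @param n Number of adults.
#' @param extent Extent \code{c(xmin, xmax, ymin, ymax)} in metres.
#' @param pattern \code{"uniform"} (default), \code{"clustered"}
#'   (Thomas-style parent/offspring placement) or \code{"grid"}
#'   (regular lattice with a small jitter).
#' @param cluster_sd Offspring displacement SD for the clustered
#'   pattern (default 10 m).
#' @param mean_cluster_size Mean offspring per parent (default 20).
#' @param seed Optional integer seed.
#' @return An \code{adult_population} with heights uniform on
#'   [3, 20] m.
#' @export
gen_adult_map <- function(n, extent = c(0, 100, 0, 100),
                          pattern = c("uniform", "clustered", "grid"),
                          cluster_sd = 10, mean_cluster_size = 20,
                          seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(adult_population())
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (pattern == "uniform") {
    x <- stats::runif(n, extent[1], extent[2])
    y <- stats::runif(n, extent[3], extent[4])
  } else if (pattern == "clustered") {
    n_par <- max(1, round(n / mean_cluster_size))
    px <- stats::runif(n_par, extent[1], extent[2])
    py <- stats::runif(n_par, extent[3], extent[4])
    pick <- sample.int(n_par, n, replace = TRUE)
    x <- pmin(pmax(px[pick] + stats::rnorm(n, 0, cluster_sd), extent[1]),
              extent[2])
    y <- pmin(pmax(py[pick] + stats::rnorm(n, 0, cluster_sd), extent[3]),
              extent[4])
  } else {
    nx <- ceiling(sqrt(n * w / h)); ny <- ceiling(n / nx)
    gx <- (rep(seq_len(nx), ny) - 0.5) * w / nx + extent[1]
    gy <- (rep(seq_len(ny), each = nx) - 0.5) * h / ny + extent[3]
    x <- gx[seq_len(n)]; y <- gy[seq_len(n)]
  }
  adult_population(id = seq_len(n), x = x, y = y,
                   height = stats::runif(n, 3, 20))
}

#' Generate a quadrat seedling survey
#'
#' Quadrat centres are placed uniformly in the extent; per-quadrat
#' ground-cover fractions are Dirichlet-distributed over the truth's
#' cover classes; seedling counts are Poisson with the truth's
#' dispersal kernel, STR and favorabilities.
#'
#' @param adults An \code{adult_population} (the seed sources).
#' @param truth A \code{truth_bundle}.
#' @param n_quadrats Number of quadrats.
#' @param extent Survey extent \code{c(xmin, xmax, ymin, ymax)};
#'   default the adult bounding box buffered by 20 m.
#' @param concentration Dirichlet concentration (scalar or per-class;
#'   default 2).
#' @param area_m2 Quadrat area (default 0.25 m2).
#' @param seed Optional integer seed.
#' @return A \code{quadrat_survey} with attribute \code{"truth"}.
#' @export
gen_quadrat_survey <- function(adults, truth, n_quadrats,
                               extent = NULL, concentration = 2,
                               area_m2 = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(extent))
    extent <- c(min(adults$x) - 20, max(adults$x) + 20,
                min(adults$y) - 20, max(adults$y) + 20)
  x <- stats::runif(n_quadrats, extent[1], extent[2])
  y <- stats::runif(n_quadrats, extent[3], extent[4])
  classes <- names(truth$favorability)
  nc <- length(classes)
  conc <- rep_len(concentration, nc)
  gmat <- matrix(stats::rgamma(n_quadrats * nc, shape = rep(conc,
                                                            each = n_quadrats)),
                 n_quadrats, nc)
  cover <- gmat / rowSums(gmat)
  colnames(cover) <- classes
  distmat <- sqrt(outer(x, adults$x, "-")^2 + outer(y, adults$y, "-")^2)
  Dsum <- .quadrat_kernel_sum(distmat, truth$kernel)
  str_eff <- truth$production$str_total * truth$production$str_multiplier
  lam <- area_m2 * as.vector(cover %*% truth$favorability) * str_eff * Dsum
  counts <- stats::rpois(n_quadrats, lam)
  out <- quadrat_survey(data.frame(x = x, y = y, count = counts),
                        cover, adults, area_m2)
  attr(out, "truth") <- truth
  attr(out, "lambda") <- lam
  out
}

#' Generate multi-year transect tier-count series
#'
#' Plot-level juvenile pools evolve by the simulator's stochastic
#' transition law (including the one-cycle holding pool for new
#' recruits), with Poisson recruitment, truncated-normal annual
#' browsing per transect, and logit-normal plot and year random
#' effects on tier-1 survival. Observed tier-1 counts merge the
#' holding pool and the 0-2 m pool, as a field survey would.
#'
#' @param truth A \code{truth_bundle}.
#' @param n_transects,n_plots,n_years Design (defaults 6, 10, 8).
#' @param browse_means Mean browsing per transect; default evenly
#'   spaced on [0.05, 0.9] to span a browsing gradient.
#' @param init_n1,init_n2 Initial pool sizes per plot (defaults 150,
#'   30).
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{transect}, \code{plot},
#'   \code{year}, \code{n1}, \code{n2}, \code{browsed}; attribute
#'   \code{"truth"}.
#' @export
gen_transect_series <- function(truth, n_transects = 6, n_plots = 10,
                                n_years = 8, browse_means = NULL,
                                init_n1 = 150, init_n2 = 30,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(browse_means))
    browse_means <- seq(0.05, 0.9, length.out = n_transects)
  st <- truth$stages
  rows <- vector("list", n_transects * n_plots)
  k <- 0
  for (tr in seq_len(n_transects)) {
    # interannual variation realized per transect (transects span
    # different parts of the landscape)
    year_eff <- stats::rnorm(n_years, 0, truth$year_sd)
    b_t <- rtruncnorm(n_years, browse_means[tr], 0.13, 0, 1)
    for (p in seq_len(n_plots)) {
      plot_eff <- stats::rnorm(1, 0, truth$plot_sd)
      n_new <- 0L; n1 <- as.integer(init_n1); n2 <- as.integer(init_n2)
      rec <- data.frame(transect = tr, plot = p, year = seq_len(n_years),
                        n1 = NA_integer_, n2 = NA_integer_,
                        browsed = b_t)
      for (yr in seq_len(n_years)) {
        if (yr > 1) {
          m <- browsing_modifier(b_t[yr - 1], truth$browsing_effect)
          s1 <- stats::plogis(stats::qlogis(st$s1) + plot_eff +
                                year_eff[yr - 1]) * m
          g1 <- st$g1 * m; s2 <- st$s2 * m; g2 <- st$g2 * m
          new_surv <- stats::rbinom(1, n_new, s1)
          n1_surv <- stats::rbinom(1, n1, s1)
          n1_adv <- stats::rbinom(1, n1_surv, g1)
          n2_surv <- stats::rbinom(1, n2, s2)
          grads <- stats::rbinom(1, n2_surv, g2)
          n_new <- stats::rpois(1, truth$recruit_rate)
          n1 <- new_surv + n1_surv - n1_adv
          n2 <- n1_adv + n2_surv - grads
        }
        rec$n1[yr] <- n1 + n_new
        rec$n2[yr] <- n2
      }
      k <- k + 1
      rows[[k]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  out
}

#' Generate a diameter sample from the equilibrium size structure
#'
#' Inverse-CDF sampling from the demographic-equilibrium diameter
#' density implied by the truth's growth law and mortality (see
#' [fit_adult_mortality()]).
#'
#' @param truth A \code{truth_bundle} (its \code{adult} parameters
#'   supply the growth law and mortality).
#' @param n Sample size (default 40, an increment-core campaign).
#' @param range Diameter range \code{c(d_lo, d_hi)} in cm; default from
#'   3-m and 28-m tree heights.
#' @param growth_fn Optional diameter growth function (cm/y); default
#'   derived from the truth's adult parameters.
#' @param seed Optional integer seed.
#' @return Numeric vector of diameters (cm); attribute \code{"truth"}.
#' @export
gen_dbh_sample <- function(truth, n = 40, range = NULL,
                           growth_fn = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- truth$adult
  if (is.null(growth_fn))
    growth_fn <- function(dd) {
      h <- height_from_dbh(dd, params)
      height_growth_rate(pmax(h, 3), params) * params$hd_a *
        params$hd_b * (h - 1.3)^(params$hd_b - 1)
    }
  if (is.null(range))
    range <- c(dbh_from_height(3, params), dbh_from_height(28, params))
  gr <- .growth_time_grid(growth_fn, range[1], range[2])
  m <- params$mortality_m
  cdf <- 1 - exp(-m * gr$T)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  d <- stats::approx(cdf, gr$d, xout = u, ties = "ordered")$y
  attr(d, "truth") <- truth
  d
}
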