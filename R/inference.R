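#' Quadrat seedling survey
#'
#' Container for the recruitment survey used to fit the dispersal
#' kernel: quadrat centres and seedling counts, per-quadrat ground
#' cover fractions by class, and the companion adult map.
#'
#' @param quadrats Data frame with columns \code{x}, \code{y},
#'   \code{count}.
#' @param cover Matrix (quadrats x classes) of ground-cover fractions,
#'   rows summing to at most 1; column names are the class labels.
#' @param adults An \code{adult_population} (or data frame with
#'   \code{x}, \code{y}).
#' @param area_m2 Quadrat area in m2 (default 0.25, a 0.5 x 0.5 m
#'   quadrat).
#' @return Object of class \code{"quadrat_survey"}.
#' @export
quadrat_survey <- function(quadrats, cover, adults, area_m2 = 0.25) {
  stopifnot(nrow(quadrats) == nrow(cover), all(quadrats$count >= 0),
            all(cover >= 0), all(rowSums(cover) <= 1 + 1e-8))
  if (is.null(colnames(cover)))
    colnames(cover) <- paste0("class", seq_len(ncol(cover)))
  structure(list(quadrats = quadrats, cover = as.matrix(cover),
                 adults = adults, area_m2 = area_m2),
            class = "quadrat_survey")
}

# per-quadrat summed kernel density over adults, for a given kernel
.quadrat_kernel_sum <- function(distmat, kernel) {
  D <- kernel_density(distmat, kernel)
  dim(D) <- dim(distmat)
  rowSums(D)
}

# negative Poisson log-likelihood factory for the dispersal fit
.dispersal_nll <- function(survey, distmat, family) {
  y <- survey$quadrats$count
  cov <- survey$cover
  nc <- ncol(cov)
  area <- survey$area_m2
  function(theta) {
    if (family == "lognormal") {
      kern <- tryCatch(dispersal_kernel(exp(theta[1]), exp(theta[2])),
                       error = function(e) NULL)
      k0 <- 2
    } else {
      kern <- tryCatch(negexp_kernel(exp(theta[1])),
                       error = function(e) NULL)
      k0 <- 1
    }
    if (is.null(kern)) return(1e10)
    str_tot <- exp(theta[k0 + 1])
    w <- c(1, exp(theta[(k0 + 2):(k0 + nc)]))[seq_len(nc)]
    fav <- as.vector(cov %*% w)
    lam <- area * fav * str_tot * .quadrat_kernel_sum(distmat, kern)
    lam <- pmax(lam, 1e-12)
    nll <- -sum(stats::dpois(y, lam, log = TRUE))
    if (!is.finite(nll)) 1e10 else nll
  }
}

# fit one kernel family by multi-start Nelder-Mead
.fit_dispersal_family <- function(survey, distmat, family, n_starts = 3) {
  y <- survey$quadrats$count
  nc <- ncol(survey$cover)
  nll <- .dispersal_nll(survey, distmat, family)
  # moment-flavoured start: total counts determine the STR scale
  str0 <- max(sum(y) / max(sum(survey$area_m2 *
                                 .quadrat_kernel_sum(distmat,
                                                     dispersal_kernel())),
                           1e-9), 1)
  base <- if (family == "lognormal")
    c(log(1), log(1), log(str0), rep(0, nc - 1))
  else
    c(log(2), log(str0), rep(0, nc - 1))
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- base + if (s == 1) 0 else stats::rnorm(length(base), 0, 0.4)
    op <- stats::optim(st, nll, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  best
}

#' Fit the dispersal/recruitment inverse model
#'
#' Jointly estimates the dispersal kernel shape, the potential-recruit
#' total per adult (STR) and the relative favorability of each
#' ground-cover class from quadrat seedling counts, by maximizing the
#' Poisson likelihood of the counts. The per-quadrat mean is
#' \deqn{\lambda_q = A \, (\sum_c f_c \, cover_{qc}) \, STR
#'   \sum_a D(r_{aq}),}
#' i.e. recruitment accumulated over the survey window. Favorabilities
#' are identified up to scale against STR, so they are normalized to
#' \code{max(f) = 1} after fitting. Both the log-normal and the
#' negative-exponential kernel family are fitted and compared by AIC.
#'
#' @param survey A \code{quadrat_survey}.
#' @param window_years Accumulation window represented by the counts
#'   (default 27); stored for constructing a simulator configuration.
#' @param n_boot Nonparametric bootstrap replicates (resampling
#'   quadrats) for 95\% CIs; 0 (default) skips the bootstrap.
#' @param n_starts Random multi-starts per kernel family (default 3).
#' @return Object of class \code{"dispersal_fit"}: chosen kernel
#'   family, \code{mode_m} and \code{log_sd} (log-normal) or
#'   \code{scale_m} (negative exponential), \code{str_total},
#'   \code{favorability} (named, max 1), per-family \code{logLik} and
#'   \code{aic}, bootstrap CIs (if requested) and a \code{boundary}
#'   flag (all-zero counts push STR to zero; no convergence is claimed
#'   there).
#' @export
fit_dispersal <- function(survey, window_years = 27, n_boot = 0,
                          n_starts = 3) {
  stopifnot(inherits(survey, "quadrat_survey"))
  if (ncol(survey$cover) < 2)
    stop("at least two ground-cover classes are required")
  if (nrow(survey$adults) == 0) stop("adults are required")
  classes <- colnames(survey$cover)
  distmat <- sqrt(outer(survey$quadrats$x, survey$adults$x, "-")^2 +
                  outer(survey$quadrats$y, survey$adults$y, "-")^2)
  if (all(survey$quadrats$count == 0)) {
    return(structure(list(boundary = TRUE, str_total = 0,
                          favorability = stats::setNames(rep(NA, length(classes)),
                                                         classes)),
                     class = "dispersal_fit"))
  }
  fits <- list(lognormal = .fit_dispersal_family(survey, distmat,
                                                 "lognormal", n_starts),
               negexp = .fit_dispersal_family(survey, distmat,
                                              "negexp", n_starts))
  npar <- c(lognormal = 2 + ncol(survey$cover),
            negexp = 1 + ncol(survey$cover))
  ll <- -vapply(fits, `[[`, numeric(1), "value")
  aic <- 2 * npar - 2 * ll
  fam <- names(which.min(aic))
  unpack <- function(theta, family) {
    nc <- ncol(survey$cover)
    k0 <- if (family == "lognormal") 2 else 1
    w <- c(1, exp(theta[(k0 + 2):(k0 + nc)]))[seq_len(nc)]
    f <- w / max(w)
    out <- list(str_total = exp(theta[k0 + 1]) * max(w),
                favorability = stats::setNames(f, classes))
    if (family == "lognormal") {
      out$mode_m <- exp(theta[1]); out$log_sd <- exp(theta[2])
    } else out$scale_m <- exp(theta[1])
    out
  }
  est <- unpack(fits[[fam]]$par, fam)
  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    nq <- nrow(survey$quadrats)
    bvals <- matrix(NA_real_, n_boot, 2 + length(classes),
                    dimnames = list(NULL, c("mode_or_scale", "str_total",
                                            classes)))
    nllb_start <- fits[[fam]]$par
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nq, nq, replace = TRUE)
      sv <- survey
      sv$quadrats <- survey$quadrats[idx, ]
      sv$cover <- survey$cover[idx, , drop = FALSE]
      dm <- distmat[idx, , drop = FALSE]
      op <- stats::optim(nllb_start, .dispersal_nll(sv, dm, fam),
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-9))
      eb <- unpack(op$par, fam)
      bvals[b, ] <- c(if (fam == "lognormal") eb$mode_m else eb$scale_m,
                      eb$str_total, eb$favorability)
    }
    boot <- bvals
    ci <- apply(bvals, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(c(est,
              list(family = fam, logLik = ll, aic = aic,
                   window_years = window_years, boundary = FALSE,
                   boot = boot, ci = ci)),
            class = "dispersal_fit")
}

#' @export
print.dispersal_fit <- function(x, ...) {
  if (isTRUE(x$boundary)) {
    cat("Dispersal fit: boundary (all counts zero, STR -> 0)\n")
    return(invisible(x))
  }
  cat(sprintf("Dispersal fit (%s kernel, AIC %.1f vs %.1f):\n", x$family,
              x$aic[[x$family]], x$aic[[setdiff(names(x$aic), x$family)]]))
  if (x$family == "lognormal")
    cat(sprintf("  mode %.3f m, log-sd %.3f\n", x$mode_m, x$log_sd))
  else
    cat(sprintf("  scale %.3f m\n", x$scale_m))
  cat(sprintf("  STR %.0f recruits per adult over %d years\n",
              x$str_total, x$window_years))
  cat("  favorability:",
      paste(sprintf("%s %.2f", names(x$favorability), x$favorability),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dispersal_fit <- function(object, ...) {
  c(if (object$family == "lognormal")
      c(mode_m = object$mode_m, log_sd = object$log_sd)
    else c(scale_m = object$scale_m),
    str_total = object$str_total, object$favorability)
}

# negative log-likelihood of the stage-rate model
.stage_nll_factory <- function(series) {
  # consecutive-year pairs within each plot
  key <- interaction(series$transect, series$plot, drop = TRUE)
  ord <- order(key, series$year)
  s <- series[ord, ]
  key <- key[ord]
  same <- key[-1] == key[-length(key)] &
    s$year[-1] == s$year[-nrow(s)] + 1
  i_prev <- which(same); i_next <- i_prev + 1
  n1p <- s$n1[i_prev]; n2p <- s$n2[i_prev]
  n1n <- s$n1[i_next]; n2n <- s$n2[i_next]
  bp <- s$browsed[i_prev]
  function(theta) {
    s1 <- stats::plogis(theta[1]); g1 <- stats::plogis(theta[2])
    s2 <- stats::plogis(theta[3]); g2 <- stats::plogis(theta[4])
    delta <- stats::plogis(theta[5]); r <- exp(theta[6])
    m <- 1 - delta * bp
    e1 <- n1p * s1 * m * (1 - g1 * m) + r
    e2 <- n2p * s2 * m * (1 - g2 * m) + n1p * s1 * m * g1 * m
    nll <- -sum(stats::dpois(n1n, pmax(e1, 1e-10), log = TRUE)) -
      sum(stats::dpois(n2n, pmax(e2, 1e-10), log = TRUE))
    if (!is.finite(nll)) 1e10 else nll
  }
}

.stage_fit_once <- function(series, start = NULL) {
  nll <- .stage_nll_factory(series)
  if (is.null(start))
    start <- c(stats::qlogis(0.9), stats::qlogis(0.01),
               stats::qlogis(0.9), stats::qlogis(0.2),
               stats::qlogis(0.4), log(5))
  op <- stats::optim(start, nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-10))
  op2 <- stats::optim(op$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  op2
}

#' Fit juvenile stage rates from transect count series
#'
#' Estimates the annual survival and transition probabilities of the
#' two juvenile height tiers, the maximal browsing effect and a
#' recruitment inflow from multi-year tier counts, by maximizing the
#' one-step conditional Poisson likelihood of each year's counts given
#' the previous year's. The transition law is the simulator's: with
#' modifier \code{m = 1 - delta_max * b},
#' \code{E[n1'] = n1 s1 m (1 - g1 m) + r} and
#' \code{E[n2'] = n2 s2 m (1 - g2 m) + n1 s1 m g1 m}. Uncertainty is
#' quantified by a nonparametric bootstrap over plots, which also
#' absorbs plot- and year-level heterogeneity; plot and year variance
#' components of survival are reported as moment estimates from
#' aggregated observed/expected ratios.
#'
#' @param series Data frame with columns \code{transect}, \code{plot},
#'   \code{year}, \code{n1} (0-2 m count), \code{n2} (2-3 m count),
#'   \code{browsed} (browsed fraction of leader stems, in [0, 1]).
#' @param n_boot Bootstrap replicates (default 50).
#' @return Object of class \code{"stage_fit"}: estimates \code{s1},
#'   \code{g1}, \code{s2}, \code{g2}, \code{delta_max},
#'   \code{recruit_rate}; 95\% bootstrap intervals in \code{$ci};
#'   \code{plot_sd}/\code{year_sd} variance components (log scale);
#'   \code{delta_identifiable} flag (FALSE when browsing does not vary
#'   in the data).
#' @export
fit_stage_rates <- function(series, n_boot = 50) {
  req <- c("transect", "plot", "year", "n1", "n2", "browsed")
  if (!all(req %in% names(series)))
    stop("series needs columns ", paste(req, collapse = ", "))
  if (length(unique(series$year)) < 2)
    stop("at least two years per plot are required")
  delta_ok <- stats::sd(series$browsed) > 1e-10
  op <- .stage_fit_once(series)
  th <- op$par
  est <- list(s1 = stats::plogis(th[1]), g1 = stats::plogis(th[2]),
              s2 = stats::plogis(th[3]), g2 = stats::plogis(th[4]),
              delta_max = if (delta_ok) stats::plogis(th[5]) else NA_real_,
              recruit_rate = exp(th[6]))
  # two-stage bootstrap: transects, then plots within each transect, so
  # that both interannual (transect-level) and spatial (plot-level)
  # heterogeneity propagate into the intervals
  ci <- NULL; boot <- NULL
  if (n_boot > 0) {
    transects <- unique(series$transect)
    nb <- matrix(NA_real_, n_boot, 6,
                 dimnames = list(NULL, c("s1", "g1", "s2", "g2",
                                         "delta_max", "recruit_rate")))
    for (b in seq_len(n_boot)) {
      take_tr <- sample(transects, length(transects), replace = TRUE)
      parts <- list(); k <- 0
      for (ti in seq_along(take_tr)) {
        tr_rows <- series[series$transect == take_tr[ti], ]
        plots <- unique(tr_rows$plot)
        take_pl <- sample(plots, length(plots), replace = TRUE)
        for (pi in seq_along(take_pl)) {
          sub <- tr_rows[tr_rows$plot == take_pl[pi], ]
          k <- k + 1
          sub$plot <- k  # keep resampled copies distinct
          sub$transect <- 1
          parts[[k]] <- sub
        }
      }
      sb <- do.call(rbind, parts)
      opb <- .stage_fit_once(sb, start = th)
      nb[b, ] <- c(stats::plogis(opb$par[1:4]), stats::plogis(opb$par[5]),
                   exp(opb$par[6]))
    }
    boot <- nb
    ci <- apply(nb, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    if (!delta_ok) ci[, "delta_max"] <- NA_real_
  }
  # moment-based variance components of tier-1 survival (log scale)
  m <- 1 - (if (delta_ok) est$delta_max else 0) * series$browsed
  comp_sd <- function(group) {
    agg_o <- tapply(series$n1, group, sum)
    agg_e <- tapply(series$n1 * est$s1 * m, group, sum)
    lr <- log(pmax(agg_o, 0.5) / pmax(agg_e, 0.5))
    stats::sd(lr)
  }
  structure(c(est, list(
    ci = ci, boot = boot,
    plot_sd = comp_sd(interaction(series$transect, series$plot)),
    year_sd = comp_sd(series$year),
    delta_identifiable = delta_ok, logLik = -op$value)),
    class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("Juvenile stage-rate fit (one-step conditional Poisson ML):\n")
  fmt <- function(nm, v) {
    if (!is.null(x$ci) && !any(is.na(x$ci[, nm])))
      sprintf("  %-12s %.4f (95%% CI %.4f - %.4f)\n", nm, v,
              x$ci[1, nm], x$ci[2, nm])
    else sprintf("  %-12s %.4f\n", nm, v)
  }
  for (nm in c("s1", "g1", "s2", "g2"))
    cat(fmt(nm, x[[nm]]))
  if (x$delta_identifiable) cat(fmt("delta_max", x$delta_max))
  else cat("  delta_max    unidentifiable (no browsing variation)\n")
  cat(sprintf("  recruit rate %.2f per plot-year\n", x$recruit_rate))
  cat(sprintf("  plot/year survival variance components (log scale): %.3f / %.3f\n",
              x$plot_sd, x$year_sd))
  invisible(x)
}

#' @export
coef.stage_fit <- function(object, ...) {
  c(s1 = object$s1, g1 = object$g1, s2 = object$s2, g2 = object$g2,
    delta_max = object$delta_max, recruit_rate = object$recruit_rate)
}

# time-to-grow integral T(d) on a grid, and interpolators
.growth_time_grid <- function(growth_fn, d_lo, d_hi, n_grid = 2000) {
  d <- seq(d_lo, d_hi, length.out = n_grid)
  g <- growth_fn(d)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("growth function must be positive over the diameter range")
  inv <- 1 / g
  Tg <- c(0, cumsum((inv[-1] + inv[-n_grid]) / 2 * diff(d)))
  list(d = d, g = g, T = Tg)
}

#' Fit density-independent adult mortality from a size structure
#'
#' Under constant recruitment into the smallest size, growth \code{g(d)}
#' and a constant annual mortality hazard \code{m}, the equilibrium
#' diameter distribution is
#' \deqn{\phi(d) \propto \frac{1}{g(d)} e^{-m T(d)}, \quad
#'   T(d) = \int_{d_0}^{d} \frac{dz}{g(z)},}
#' normalized over the diameter range. \code{m} is estimated by maximum
#' likelihood from a sample of diameters, with a 95\% profile-likelihood
#' interval.
#'
#' @param diameters Sample of dbh values (cm), length >= 20.
#' @param growth_fn Diameter growth function, cm/y as a function of dbh
#'   (cm). Default: the adult height-growth law of [adult_params()]
#'   converted through the height-diameter allometry.
#' @param params An \code{adult_params} (for the default growth_fn).
#' @param range Normalization range \code{c(d_lo, d_hi)}; default the
#'   observed range.
#' @param m_max Upper bound of the mortality search (default 0.5).
#' @return Object of class \code{"mortality_fit"}: \code{m},
#'   \code{ci}, \code{logLik}, and the profile table in \code{$profile}.
#' @export
fit_adult_mortality <- function(diameters, growth_fn = NULL,
                                params = adult_params(), range = NULL,
                                m_max = 0.5) {
  d <- diameters
  if (length(d) < 20) stop("at least 20 diameters are required")
  if (stats::sd(d) == 0) stop("degenerate (single-valued) diameter sample")
  if (is.null(growth_fn))
    growth_fn <- function(dd) {
      h <- height_from_dbh(dd, params)
      height_growth_rate(pmax(h, 3), params) * params$hd_a *
        params$hd_b * (h - 1.3)^(params$hd_b - 1)
    }
  if (is.null(range)) range <- base::range(d)
  stopifnot(all(d >= range[1]), all(d <= range[2]))
  gr <- .growth_time_grid(growth_fn, range[1], range[2])
  Td <- stats::approx(gr$d, gr$T, xout = d)$y
  gd <- growth_fn(d)
  Tmax <- gr$T[length(gr$T)]
  nll <- function(m) {
    logZ <- if (m * Tmax < 1e-8) log(Tmax) else log1p(-exp(-m * Tmax)) - log(m)
    sum(log(gd)) + m * sum(Td) + length(d) * logZ
  }
  op <- stats::optimize(nll, c(1e-6, m_max))
  m_hat <- op$minimum
  ll_max <- -op$objective
  prof_m <- seq(max(m_hat / 5, 1e-5), min(m_hat * 5, m_max),
                length.out = 400)
  prof_ll <- -vapply(prof_m, nll, numeric(1))
  inside <- prof_ll >= ll_max - stats::qchisq(0.95, 1) / 2
  ci <- base::range(prof_m[inside])
  structure(list(m = m_hat, ci = ci, logLik = ll_max,
                 profile = data.frame(m = prof_m, logLik = prof_ll),
                 range = range, growth_fn = growth_fn),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("Adult mortality fit: m = %.4f per year (95%% profile CI %.4f - %.4f)\n",
              x$m, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.mortality_fit <- function(object, ...) c(m = object$m)
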