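#' Log-normal seed-dispersal kernel
#'
#' Isotropic per-area deposition density of recruits around a parent
#' tree. The per-area density at distance \code{r} is
#' \deqn{D(r) = g(r) / (2 \pi r),}
#' where \code{g} is the one-dimensional log-normal pdf with log-scale
#' location \code{mu_ln} and scale \code{log_sd}. The location is
#' derived from the requested modal distance of the per-area density,
#' \code{mu_ln = log(mode_m) + 2 log_sd^2}, so that \code{D(r)} peaks
#' exactly at \code{mode_m}. \code{D} integrates to 1 over the plane
#' before truncation and is treated as zero beyond the truncation
#' radius.
#'
#' @param mode_m Modal distance of the per-area density in metres
#'   (default 0.67, the fitted dispersal mode).
#' @param log_sd Log-scale standard deviation (> 0). Default 1, chosen
#'   so that the density is negligible (under 1e-5 of its peak) by
#'   100 m, matching the observed decline of seedling densities to near
#'   zero beyond that distance.
#' @param truncation_radius_m Distance beyond which the kernel is
#'   treated as exactly zero (default 100 m).
#' @return Object of class \code{"dispersal_kernel"}.
#' @export
dispersal_kernel <- function(mode_m = 0.67, log_sd = 1,
                             truncation_radius_m = 100) {
  stopifnot(mode_m > 0, log_sd > 0, truncation_radius_m > 0)
  structure(list(mode_m = mode_m, log_sd = log_sd,
                 truncation_radius_m = truncation_radius_m,
                 mu_ln = log(mode_m) + 2 * log_sd^2,
                 family = "lognormal"),
            class = "dispersal_kernel")
}

#' Negative-exponential dispersal kernel
#'
#' Alternative kernel family for model comparison in the dispersal fit:
#' \code{D(r) = exp(-r/scale) / (2 pi scale^2)}, which integrates to 1
#' over the plane.
#'
#' @param scale_m Distance scale in metres.
#' @param truncation_radius_m Truncation radius (default 100 m).
#' @return Object of class \code{"dispersal_kernel"}.
#' @export
negexp_kernel <- function(scale_m, truncation_radius_m = 100) {
  stopifnot(scale_m > 0)
  structure(list(scale_m = scale_m,
                 truncation_radius_m = truncation_radius_m,
                 family = "negexp"),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  if (x$family == "lognormal")
    cat(sprintf("Log-normal dispersal kernel: mode %.3g m, log-sd %.3g, truncated at %g m\n",
                x$mode_m, x$log_sd, x$truncation_radius_m))
  else
    cat(sprintf("Negative-exponential dispersal kernel: scale %.3g m, truncated at %g m\n",
                x$scale_m, x$truncation_radius_m))
  invisible(x)
}

#' Evaluate the per-area kernel density
#'
#' @param r Distances in metres (>= 0); vectorized.
#' @param kernel A \code{dispersal_kernel}.
#' @return Per-area weights in m^-2; zero at \code{r = 0} (limit) and
#'   beyond the truncation radius.
#' @export
kernel_density <- function(r, kernel) {
  if (any(r < 0)) stop("distances must be non-negative")
  d <- numeric(length(r))
  ok <- r > 0 & r <= kernel$truncation_radius_m
  if (kernel$family == "lognormal") {
    d[ok] <- stats::dlnorm(r[ok], meanlog = kernel$mu_ln,
                           sdlog = kernel$log_sd) / (2 * pi * r[ok])
  } else {
    d[r <= kernel$truncation_radius_m] <-
      exp(-r[r <= kernel$truncation_radius_m] / kernel$scale_m) /
      (2 * pi * kernel$scale_m^2)
    d[r == 0] <- 1 / (2 * pi * kernel$scale_m^2)
  }
  d
}

#' In-range mass of a kernel
#'
#' \eqn{\int_0^R D(r) 2 \pi r \, dr}: the fraction of seed deposition
#' retained inside the truncation radius.
#'
#' @param kernel A \code{dispersal_kernel}.
#' @return Scalar in (0, 1].
#' @export
kernel_mass <- function(kernel) {
  if (kernel$family == "lognormal")
    stats::plnorm(kernel$truncation_radius_m, kernel$mu_ln, kernel$log_sd)
  else {
    b <- kernel$truncation_radius_m / kernel$scale_m
    1 - exp(-b) * (1 + b)
  }
}

#' Per-adult recruit production
#'
#' Each adult produces a fixed total number of potential recruits (STR)
#' over the survey accumulation window; the simulator uses the
#' annualized rate \code{str_total * str_multiplier / window_years}.
#' The multiplier is the validation calibration factor (default 1.10).
#'
#' @param str_total Potential recruits per adult over the window
#'   (default 1046).
#' @param str_multiplier Calibration multiplier (default 1.10).
#' @param window_years Accumulation window in years (default 27, the
#'   recruitment period integrated by the seedling surveys).
#' @return Object of class \code{"recruit_production"} with the above
#'   fields plus \code{annual}, the per-adult annual production.
#' @export
recruit_production <- function(str_total = 1046, str_multiplier = 1.10,
                               window_years = 27) {
  stopifnot(str_total > 0, str_multiplier > 0, window_years > 0)
  structure(list(str_total = str_total, str_multiplier = str_multiplier,
                 window_years = window_years,
                 annual = str_total * str_multiplier / window_years),
            class = "recruit_production")
}

#' Expected recruitment field from an adult map
#'
#' Reference (exact) computation: for every cell the expected number of
#' new recruits per year is
#' \deqn{\lambda = F \cdot A \cdot \sum_a p \, D(d_a),}
#' with \code{F} the cell's substrate favorability, \code{A} the cell
#' area, \code{p} the per-adult annual production and \code{d_a} the
#' distance from adult \code{a} to the cell centre. Adults contribute
#' nothing beyond the kernel truncation radius.
#'
#' @param adults Adult population (see [adult_population()]), or any
#'   data frame with columns \code{x}, \code{y}.
#' @param substrate A \code{substrate_field}.
#' @param kernel A \code{dispersal_kernel}.
#' @param production A \code{recruit_production}.
#' @return Matrix of per-cell Poisson means (same shape as the
#'   substrate field).
#' @export
expected_recruitment_field <- function(adults, substrate, kernel,
                                       production) {
  grid <- substrate$grid
  lam <- matrix(0, grid$nrow, grid$ncol)
  n <- nrow(adults)
  if (is.null(n) || n == 0)
    return(lam * substrate$favorability)
  cc <- cell_centers(grid)
  csz <- grid$cell_size_m
  Rtr <- kernel$truncation_radius_m
  for (a in seq_len(n)) {
    xa <- adults$x[a]; ya <- adults$y[a]
    jr <- which(abs(cc$x - xa) <= Rtr + csz)
    ir <- which(abs(cc$y - ya) <= Rtr + csz)
    if (!length(jr) || !length(ir)) next
    dx <- cc$x[jr] - xa
    dy <- cc$y[ir] - ya
    dist <- sqrt(outer(dy^2, dx^2, "+"))
    lam[ir, jr] <- lam[ir, jr] + kernel_density(dist, kernel)
  }
  lam * production$annual * csz^2 * substrate$favorability
}

#' Cell-resolution kernel stamp
#'
#' Discrete kernel used by the simulator's fast (FFT) recruitment
#' engine: entry \code{(di, dj)} is the kernel density at the centre of
#' the cell offset \code{(di, dj)} from the source cell, averaged over
#' the source position uniform within its cell (midpoint subsampling).
#' Averaging over the within-cell source position gives the expected
#' contribution for an adult whose exact position is resolved only to
#' its cell, and keeps the self-cell weight positive (the pointwise
#' density vanishes at r = 0).
#'
#' @param kernel A \code{dispersal_kernel}.
#' @param cell_size_m Cell size in metres.
#' @param subsamples Number of midpoint subsamples per axis for the
#'   within-cell average (default 5).
#' @return Square matrix of side \code{2R + 1} cells (R = truncation
#'   radius in cells) whose entries sum to approximately
#'   [kernel_mass()].
#' @export
kernel_stamp <- function(kernel, cell_size_m = 1, subsamples = 5) {
  R <- ceiling(kernel$truncation_radius_m / cell_size_m)
  off <- (-R:R) * cell_size_m
  sub <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * cell_size_m
  K <- matrix(0, 2 * R + 1, 2 * R + 1)
  for (u in sub) for (v in sub) {
    dist <- sqrt(outer((off - v)^2, (off - u)^2, "+"))
    K <- K + kernel_density(dist, kernel)
  }
  K * cell_size_m^2 / subsamples^2
}

# 2-D linear convolution of a count field with a centred stamp, via FFT
# on a zero-padded grid; returns a matrix the shape of `A`.
conv2_stamp <- function(A, K) {
  R <- (nrow(K) - 1L) / 2L
  n1 <- stats::nextn(nrow(A) + 2L * R, c(2, 3, 5))
  n2 <- stats::nextn(ncol(A) + 2L * R, c(2, 3, 5))
  PA <- matrix(0, n1, n2); PA[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  PK <- matrix(0, n1, n2)
  idx1 <- c((n1 - R + 1):n1, 1:(R + 1))
  idx2 <- c((n2 - R + 1):n2, 1:(R + 1))
  PK[idx1, idx2] <- K  # centre of stamp wrapped to (1, 1)
  S <- Re(stats::fft(stats::fft(PA) * stats::fft(PK), inverse = TRUE)) /
    (n1 * n2)
  pmax(S[seq_len(nrow(A)), seq_len(ncol(A))], 0)
}

#' Juvenile count grid
#'
#' Per-cell integer counts of juvenile trees (< 3 m) in three pools:
#' \code{n_new} (recruits of the current annual cycle, held back from
#' advancement), \code{n1} (0-2 m tier, transition-eligible) and
#' \code{n2} (2-3 m tier). Each 1-m2 cell holds at most \code{cap_k}
#' juveniles in total.
#'
#' @param grid A \code{grid_spec}.
#' @param cap_k Per-cell cap on total juveniles (default 50).
#' @return Object of class \code{"juvenile_grid"}.
#' @export
juvenile_grid <- function(grid, cap_k = 50) {
  z <- matrix(0L, grid$nrow, grid$ncol)
  structure(list(grid = grid, n_new = z, n1 = z, n2 = z,
                 cap_k = as.integer(cap_k)),
            class = "juvenile_grid")
}

#' @export
print.juvenile_grid <- function(x, ...) {
  cat(sprintf("Juvenile grid %d x %d: %d new, %d in 0-2 m, %d in 2-3 m (cap %d per cell)\n",
              x$grid$nrow, x$grid$ncol, sum(x$n_new), sum(x$n1), sum(x$n2),
              x$cap_k))
  invisible(x)
}

#' Stochastic recruitment draw
#'
#' Draws per-cell Poisson recruit numbers from the expected-recruitment
#' field and adds them to the \code{n_new} pool, discarding any excess
#' over the per-cell cap.
#'
#' @param juveniles A \code{juvenile_grid}.
#' @param lambda_field Matrix of per-cell Poisson means (same shape).
#' @param seed Optional integer seed.
#' @return Updated \code{juvenile_grid}.
#' @export
recruit <- function(juveniles, lambda_field, seed = NULL) {
  if (any(lambda_field < 0)) stop("lambda_field must be non-negative")
  stopifnot(all(dim(lambda_field) == dim(juveniles$n1)))
  if (!is.null(seed)) set.seed(seed)
  idx <- which(lambda_field > 0)
  if (length(idx)) {
    k <- stats::rpois(length(idx), lambda_field[idx])
    room <- juveniles$cap_k -
      (juveniles$n_new[idx] + juveniles$n1[idx] + juveniles$n2[idx])
    juveniles$n_new[idx] <- juveniles$n_new[idx] +
      as.integer(pmin(k, pmax(room, 0L)))
  }
  juveniles
}
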