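#' Simulation configuration
#'
#' Bundles the landscape grid, the stochastic drivers and all submodel
#' parameters for a multi-year run.
#'
#' @param grid A \code{grid_spec}.
#' @param years Number of simulated years (default 30).
#' @param kernel A \code{dispersal_kernel}.
#' @param production A \code{recruit_production}.
#' @param stages A \code{stage_rates}.
#' @param browsing_effect A \code{browsing_effect}.
#' @param adult An \code{adult_params}.
#' @param substrate_mu,substrate_sd Truncated-normal parameters of the
#'   per-cell substrate favorability.
#' @param substrate_redraw Redraw the substrate field each year
#'   (default TRUE; favorability varies among years but not
#'   directionally)?
#' @param browsing_mu,browsing_sd Truncated-normal parameters of the
#'   annual browsing proportion.
#' @param cap_k Per-cell juvenile cap (default 50).
#' @param recruit_method \code{"fft"} (default; adults binned to cells
#'   and convolved with the cell-averaged kernel stamp) or
#'   \code{"exact"} (per-adult point-to-cell-centre sums; slower, used
#'   for small populations and cross-checks).
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(grid, years = 30,
                       kernel = dispersal_kernel(),
                       production = recruit_production(),
                       stages = stage_rates(),
                       browsing_effect = birchspread::browsing_effect(),
                       adult = adult_params(),
                       substrate_mu = 0.5, substrate_sd = 0.13,
                       substrate_redraw = TRUE,
                       browsing_mu = 0.5, browsing_sd = 0.13,
                       cap_k = 50,
                       recruit_method = c("fft", "exact")) {
  structure(list(grid = grid, years = years, kernel = kernel,
                 production = production, stages = stages,
                 browsing_effect = browsing_effect, adult = adult,
                 substrate_mu = substrate_mu, substrate_sd = substrate_sd,
                 substrate_redraw = substrate_redraw,
                 browsing_mu = browsing_mu, browsing_sd = browsing_sd,
                 cap_k = cap_k,
                 recruit_method = match.arg(recruit_method)),
            class = "sim_config")
}

#' Initialize a simulation state
#'
#' @param config A \code{sim_config}.
#' @param adults Initial \code{adult_population}.
#' @return Object of class \code{"sim_state"}: year counter, substrate
#'   field, juvenile grid, adult population, realized browsing history
#'   and the next free adult id.
#' @export
init_state <- function(config, adults = adult_population()) {
  if (nrow(adults)) {
    if (any(adults$x < 0 | adults$x > config$grid$width_m |
            adults$y < 0 | adults$y > config$grid$height_m))
      stop("adult coordinates must lie inside the landscape")
  }
  substrate <- draw_substrate_field(config$grid, config$substrate_mu,
                                    config$substrate_sd)
  structure(list(year = 0L,
                 substrate = substrate,
                 juveniles = juvenile_grid(config$grid, config$cap_k),
                 adults = adults,
                 browsing = numeric(0),
                 next_id = if (nrow(adults)) max(adults$id) + 1L else 1L,
                 stamp = NULL),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulation state, year %d: %d adults, %d juveniles (%d in 2-3 m tier)\n",
              x$year, nrow(x$adults),
              sum(x$juveniles$n_new) + sum(x$juveniles$n1) + sum(x$juveniles$n2),
              sum(x$juveniles$n2)))
  invisible(x)
}

# bin adult positions to grid cells -> integer count matrix
bin_adults <- function(adults, grid) {
  A <- matrix(0L, grid$nrow, grid$ncol)
  if (!nrow(adults)) return(A)
  csz <- grid$cell_size_m
  j <- pmin(pmax(floor(adults$x / csz), 0), grid$ncol - 1L) + 1L
  i <- pmin(pmax(floor(adults$y / csz), 0), grid$nrow - 1L) + 1L
  idx <- (j - 1L) * grid$nrow + i
  tab <- tabulate(idx, nbins = grid$nrow * grid$ncol)
  A[] <- tab
  A
}

# expected-recruitment field for the annual loop, by the configured engine
recruitment_field <- function(state, config) {
  if (config$recruit_method == "exact")
    return(expected_recruitment_field(state$adults, state$substrate,
                                      config$kernel, config$production))
  A <- bin_adults(state$adults, config$grid)
  S <- conv2_stamp(A, state$stamp)
  S * config$production$annual * state$substrate$favorability
}

#' Advance the simulation by one year
#'
#' The fixed annual routine: draw the year's browsing proportion,
#' redraw the substrate field (if enabled), recruit seedlings from the
#' current adult map, apply juvenile survival and tier transitions,
#' graduate 2-3 m survivors into 3.0-m adults, then grow and kill
#' adults and remove overtopped ones. Randomness is taken from the
#' current RNG stream; seed the stream (or use [run_simulation()]) for
#' reproducibility.
#'
#' @param state A \code{sim_state}.
#' @param config A \code{sim_config}.
#' @return Updated \code{sim_state}.
#' @export
run_year <- function(state, config) {
  if (is.null(state$stamp) && config$recruit_method == "fft")
    state$stamp <- kernel_stamp(config$kernel, config$grid$cell_size_m)
  b <- rtruncnorm(1, config$browsing_mu, config$browsing_sd, 0, 1)
  if (config$substrate_redraw || state$year == 0L)
    state$substrate <- draw_substrate_field(config$grid,
                                            config$substrate_mu,
                                            config$substrate_sd)
  lam <- recruitment_field(state, config)
  state$juveniles <- recruit(state$juveniles, lam)
  tr <- transition_step(state$juveniles, config$stages, b,
                        config$browsing_effect, mode = "stochastic")
  state$juveniles <- tr$juveniles
  new_adults <- graduate_to_adults(tr$graduates, config$grid,
                                   id_start = state$next_id)
  if (nrow(new_adults)) {
    state$next_id <- state$next_id + nrow(new_adults)
    state$adults <- rbind(state$adults, new_adults)
    class(state$adults) <- c("adult_population", "data.frame")
  }
  state$adults <- grow_and_kill_adults(state$adults, config$adult)
  state$adults <- overtopping_removal(state$adults, config$adult)
  state$browsing <- c(state$browsing, b)
  state$year <- state$year + 1L
  state
}

# one-row summary of a state
state_summary <- function(state, config) {
  data.frame(year = state$year,
             n1_total = sum(state$juveniles$n1) + sum(state$juveniles$n_new),
             n2_total = sum(state$juveniles$n2),
             adult_count = nrow(state$adults),
             adult_ba_m2 = basal_area(state$adults, config$adult))
}

#' Run a full simulation
#'
#' Executes [run_year()] for \code{config$years} years from the given
#' initial adults. The whole run is a deterministic function of
#' \code{(config, adults, seed)}.
#'
#' @param config A \code{sim_config}.
#' @param adults Initial \code{adult_population}.
#' @param seed Integer seed for the run's RNG stream.
#' @param keep_yearly Record a one-row summary per year (default TRUE).
#' @return Object of class \code{"birch_sim"}: list with \code{record}
#'   (final-year summary), \code{yearly} (per-year summaries),
#'   \code{state} (final \code{sim_state}), \code{config}, \code{seed}.
#' @export
run_simulation <- function(config, adults = adult_population(),
                           seed = NULL, keep_yearly = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(config, adults)
  yearly <- if (keep_yearly) state_summary(state, config) else NULL
  for (t in seq_len(config$years)) {
    state <- run_year(state, config)
    if (keep_yearly) yearly <- rbind(yearly, state_summary(state, config))
  }
  structure(list(record = state_summary(state, config),
                 yearly = yearly, state = state,
                 config = config, seed = seed),
            class = "birch_sim")
}

#' @export
print.birch_sim <- function(x, ...) {
  r <- x$record
  cat(sprintf("Birch invasion simulation, %d years on %g x %g m:\n",
              r$year, x$config$grid$width_m, x$config$grid$height_m))
  cat(sprintf("  juveniles 0-2 m: %d   2-3 m: %d\n", r$n1_total, r$n2_total))
  cat(sprintf("  adults: %d (basal area %.2f m2)\n",
              r$adult_count, r$adult_ba_m2))
  invisible(x)
}

#' @export
summary.birch_sim <- function(object, ...) {
  cat(sprintf("Mean realized browsing: %.3f over %d years\n",
              mean(object$state$browsing), object$record$year))
  print(object)
  invisible(object$yearly)
}

#' Initial adults for the core-invasion scenario
#'
#' Adults are positioned uniformly at random within a contiguous core
#' block centred in the landscape, with heights uniform on [3, 20] m.
#'
#' @param grid A \code{grid_spec}.
#' @param density Initial density in trees/ha (250 or 500 in the
#'   standard experiments).
#' @param core_ha Core block area in ha (default 16).
#' @param seed Optional integer seed.
#' @return An \code{adult_population} of \code{density * core_ha} trees.
#' @export
build_core_scenario <- function(grid, density, core_ha = 16,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- sqrt(core_ha * 1e4)
  stopifnot(side <= grid$width_m, side <= grid$height_m)
  x0 <- (grid$width_m - side) / 2
  y0 <- (grid$height_m - side) / 2
  n <- round(density * core_ha)
  adult_population(id = seq_len(n),
                   x = stats::runif(n, x0, x0 + side),
                   y = stats::runif(n, y0, y0 + side),
                   height = stats::runif(n, 3, 20))
}

#' Initial adults for the patch-invasion ("woodland islet") scenario
#'
#' The same total number of adults as the 500 trees/ha core model
#' (8000 by default) is divided equally among small square patches
#' placed disjointly, uniformly at random, within a central block
#' (100 ha by default). Heights are uniform on [3, 20] m.
#'
#' @param grid A \code{grid_spec}.
#' @param n_total Total adults (default 8000).
#' @param n_patches Number of patches (default 10).
#' @param patch_ha Patch area in ha (default 0.1).
#' @param block_ha Central block area in ha (default 100).
#' @param seed Optional integer seed.
#' @return An \code{adult_population}; attribute \code{"patches"} holds
#'   the patch lower-left corners and side length.
#' @export
build_patch_scenario <- function(grid, n_total = 8000, n_patches = 10,
                                 patch_ha = 0.1, block_ha = 100,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bside <- sqrt(block_ha * 1e4)
  pside <- sqrt(patch_ha * 1e4)
  stopifnot(bside <= grid$width_m, bside <= grid$height_m)
  bx0 <- (grid$width_m - bside) / 2
  by0 <- (grid$height_m - bside) / 2
  corners <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(corners) < n_patches) {
    cand <- c(stats::runif(1, bx0, bx0 + bside - pside),
              stats::runif(1, by0, by0 + bside - pside))
    ok <- !nrow(corners) ||
      all(abs(cand[1] - corners[, 1]) >= pside |
          abs(cand[2] - corners[, 2]) >= pside)
    if (ok) corners <- rbind(corners, cand)
    tries <- tries + 1
    if (tries > 1e5) stop("could not place disjoint patches")
  }
  per <- rep(n_total %/% n_patches, n_patches)
  per[seq_len(n_total %% n_patches)] <- per[seq_len(n_total %% n_patches)] + 1
  x <- y <- numeric(0)
  for (p in seq_len(n_patches)) {
    x <- c(x, stats::runif(per[p], corners[p, 1], corners[p, 1] + pside))
    y <- c(y, stats::runif(per[p], corners[p, 2], corners[p, 2] + pside))
  }
  pop <- adult_population(id = seq_len(n_total), x = x, y = y,
                          height = stats::runif(n_total, 3, 20))
  attr(pop, "patches") <- list(corners = unname(corners), side = pside)
  pop
}

# reproducible per-run seed from a master seed and a run index
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 16807) %% 2147483647)
}

#' Enumerate a scenario experiment
#'
#' Builds the full factorial plan of one scenario configuration: every
#' combination of mean browsing level, mean substrate favorability and
#' replicate, with reproducible per-run and per-replicate seeds derived
#' from a master seed. With the default 11 x 11 gradient there are 121
#' factor combinations and, at 100 replicates, 12100 runs.
#'
#' @param browse_means Grid of mean browsing proportions
#'   (default \code{seq(0, 1, 0.1)}).
#' @param substrate_means Grid of mean substrate favorabilities
#'   (default \code{seq(0, 1, 0.1)}).
#' @param reps Replicates per combination (default 100).
#' @param configuration \code{"core"} or \code{"patch"}.
#' @param density Initial adult density, trees/ha (core model).
#' @param master_seed Master seed for derived per-run seeds.
#' @return Data frame with one row per run: \code{configuration},
#'   \code{density}, \code{mu_b}, \code{mu_s}, \code{replicate},
#'   \code{seed}, \code{adult_seed}. The adult seed depends only on the
#'   replicate, so all gradient levels of a replicate share the same
#'   initial adult map (common random numbers).
#' @export
scenario_plan <- function(browse_means = seq(0, 1, 0.1),
                          substrate_means = seq(0, 1, 0.1),
                          reps = 100, configuration = c("core", "patch"),
                          density = 500, master_seed = 1) {
  configuration <- match.arg(configuration)
  plan <- expand.grid(replicate = seq_len(reps),
                      mu_s = substrate_means, mu_b = browse_means,
                      KEEP.OUT.ATTRS = FALSE)
  plan <- plan[, c("mu_b", "mu_s", "replicate")]
  plan$configuration <- configuration
  plan$density <- density
  plan$seed <- derive_seed(master_seed, seq_len(nrow(plan)))
  plan$adult_seed <- derive_seed(master_seed + 104729, plan$replicate)
  plan
}

#' Run a scenario grid
#'
#' Executes every run of a [scenario_plan()] and returns one record per
#' run with the year-30 (final-year) outputs.
#'
#' @param config A \code{sim_config} (its grid and years apply to every
#'   run; browsing and substrate means are overridden per run).
#' @param plan A [scenario_plan()] data frame.
#' @param core_ha Core block area in ha for the core configuration
#'   (default 16).
#' @param patch_args Named list of arguments forwarded to
#'   [build_patch_scenario()] for patch-configuration runs (e.g. scaled
#'   patch counts on a reduced landscape).
#' @param progress Print a line per completed run (default FALSE).
#' @return The plan with appended output columns \code{n1_total},
#'   \code{n2_total}, \code{adult_count}, \code{adult_ba_m2},
#'   \code{initial_ba_m2}.
#' @export
run_scenario_grid <- function(config, plan, core_ha = 16,
                              patch_args = list(), progress = FALSE) {
  out <- plan
  out$n1_total <- out$n2_total <- out$adult_count <- NA_real_
  out$adult_ba_m2 <- out$initial_ba_m2 <- NA_real_
  adult_cache <- list()
  for (r in seq_len(nrow(plan))) {
    key <- paste(plan$configuration[r], plan$density[r],
                 plan$adult_seed[r])
    if (is.null(adult_cache[[key]])) {
      adult_cache[[key]] <-
        if (plan$configuration[r] == "core")
          build_core_scenario(config$grid, plan$density[r], core_ha,
                              seed = plan$adult_seed[r])
        else
          do.call(build_patch_scenario,
                  c(list(config$grid, seed = plan$adult_seed[r]),
                    patch_args))
    }
    adults <- adult_cache[[key]]
    cfg <- config
    cfg$browsing_mu <- plan$mu_b[r]
    cfg$substrate_mu <- plan$mu_s[r]
    sim <- run_simulation(cfg, adults, seed = plan$seed[r],
                          keep_yearly = FALSE)
    out$n1_total[r] <- sim$record$n1_total
    out$n2_total[r] <- sim$record$n2_total
    out$adult_count[r] <- sim$record$adult_count
    out$adult_ba_m2[r] <- sim$record$adult_ba_m2
    out$initial_ba_m2[r] <- basal_area(adults, config$adult)
    if (progress)
      message(sprintf("run %d/%d: mu_b=%.1f mu_s=%.1f rep=%d BA=%.1f",
                      r, nrow(plan), plan$mu_b[r], plan$mu_s[r],
                      plan$replicate[r], out$adult_ba_m2[r]))
  }
  out
}

#' Aboveground carbon stock of tall adults
#'
#' Counts adults taller than the reference height and multiplies by the
#' per-tree carbon content of a tree of that stature (an 8.5-m birch
#' holds about 10.4 kg C).
#'
#' @param pop An \code{adult_population}.
#' @param per_tree_kg_c Carbon per qualifying tree in kg (default 10.4).
#' @param min_height_m Qualifying height threshold in m (default 8.5).
#' @return Carbon stock in tonnes.
#' @export
carbon_stock <- function(pop, per_tree_kg_c = 10.4, min_height_m = 8.5) {
  if (!nrow(pop)) return(0)
  sum(pop$height > min_height_m) * per_tree_kg_c / 1000
}
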