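#' Juvenile stage rates
#'
#' Annual survival and transition probabilities of the two juvenile
#' height tiers. Transitions are conditional on survival: a 0-2 m tree
#' survives with probability \code{s1} and, given survival, advances to
#' the 2-3 m tier with probability \code{g1}; a 2-3 m tree survives
#' with probability \code{s2} and, given survival, graduates to the
#' adult layer (3 m) with probability \code{g2}. Defaults sit inside
#' the fitted credible intervals: survival near the upper end of the
#' 75-100\% interval for both tiers, a 0-2 m transition at the midpoint
#' of its 0.1-1.2\% interval, and a much higher 2-3 m transition.
#'
#' @param s1 Annual survival, 0-2 m tier (default 0.95).
#' @param g1 Advance probability given survival, 0-2 m tier
#'   (default 0.0065).
#' @param s2 Annual survival, 2-3 m tier (default 0.95).
#' @param g2 Graduation probability given survival, 2-3 m tier
#'   (default 0.20).
#' @return Object of class \code{"stage_rates"}.
#' @export
stage_rates <- function(s1 = 0.95, g1 = 0.0065, s2 = 0.95, g2 = 0.20) {
  for (p in c(s1, g1, s2, g2))
    if (!is.finite(p) || p < 0 || p > 1) stop("rates must be in [0, 1]")
  structure(list(s1 = s1, g1 = g1, s2 = s2, g2 = g2),
            class = "stage_rates")
}

#' Browsing effect on juvenile rates
#'
#' Deer browsing reduces all four juvenile rates multiplicatively and
#' linearly in the annual browsing proportion \code{b}: the modifier is
#' \code{1 - delta_max * b}. With the default \code{delta_max = 0.48},
#' complete browsing (b = 1) gives the maximal fitted 48\% reduction
#' and b of about 0.21 the mean fitted 10\% reduction.
#'
#' @param delta_max Maximal proportional reduction at b = 1
#'   (default 0.48).
#' @return Object of class \code{"browsing_effect"}.
#' @export
browsing_effect <- function(delta_max = 0.48) {
  stopifnot(is.finite(delta_max), delta_max >= 0, delta_max <= 1)
  structure(list(delta_max = delta_max), class = "browsing_effect")
}

#' Browsing rate modifier
#'
#' @param b Annual browsing proportion in [0, 1].
#' @param effect A \code{browsing_effect}.
#' @return Multiplier \code{1 - delta_max * b}, applied to all four
#'   juvenile stage rates.
#' @export
browsing_modifier <- function(b, effect = browsing_effect()) {
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    stop("browsing proportion must be in [0, 1]")
  1 - effect$delta_max * b
}

#' Annual juvenile transition step
#'
#' Applies one year of survival, tier advancement and graduation to the
#' juvenile grid under browsing-modified rates. Trees in \code{n_new}
#' (recruits of the current cycle) survive at the 0-2 m rate but cannot
#' advance; survivors enter \code{n1} and become transition-eligible at
#' the next step. In stochastic mode per-cell fates are binomial draws;
#' expected mode propagates real-valued expectations and is intended
#' for testing and analysis only.
#'
#' @param juveniles A \code{juvenile_grid}.
#' @param rates A \code{stage_rates}.
#' @param b Annual browsing proportion in [0, 1].
#' @param effect A \code{browsing_effect}.
#' @param mode \code{"stochastic"} (default) or \code{"expected"}.
#' @param seed Optional integer seed.
#' @return List with \code{juveniles} (updated grid) and
#'   \code{graduates} (per-cell counts removed from \code{n2} into the
#'   adult layer).
#' @export
transition_step <- function(juveniles, rates, b,
                            effect = browsing_effect(),
                            mode = c("stochastic", "expected"),
                            seed = NULL) {
  mode <- match.arg(mode)
  m <- browsing_modifier(b, effect)
  s1 <- rates$s1 * m; g1 <- rates$g1 * m
  s2 <- rates$s2 * m; g2 <- rates$g2 * m
  dims <- dim(juveniles$n1)
  if (mode == "stochastic") {
    if (!is.null(seed)) set.seed(seed)
    draw <- function(n, p) {
      out <- n * 0L
      idx <- which(n > 0)
      if (length(idx)) out[idx] <- stats::rbinom(length(idx), n[idx], p)
      out
    }
    new_surv <- draw(juveniles$n_new, s1)          # survive, cannot advance
    n1_surv <- draw(juveniles$n1, s1)              # tier-1 survivors
    n1_adv <- draw(n1_surv, g1)                    # advance given survival
    n2_surv <- draw(juveniles$n2, s2)
    grads <- draw(n2_surv, g2)
    juveniles$n_new <- matrix(0L, dims[1], dims[2])
    juveniles$n1 <- new_surv + n1_surv - n1_adv
    juveniles$n2 <- n1_adv + n2_surv - grads
  } else {
    new_surv <- juveniles$n_new * s1
    n1_surv <- juveniles$n1 * s1
    n1_adv <- n1_surv * g1
    n2_surv <- juveniles$n2 * s2
    grads <- n2_surv * g2
    juveniles$n_new <- matrix(0, dims[1], dims[2])
    juveniles$n1 <- new_surv + n1_surv - n1_adv
    juveniles$n2 <- n1_adv + n2_surv - grads
  }
  list(juveniles = juveniles, graduates = grads)
}

#' Turn graduating juveniles into adult trees
#'
#' Each graduate becomes a 3.0-m adult positioned uniformly at random
#' within its source cell, with a fresh unique id.
#'
#' @param graduates Matrix of per-cell graduate counts.
#' @param grid The \code{grid_spec} the counts refer to.
#' @param id_start First id to assign (default 1).
#' @param seed Optional integer seed.
#' @return An [adult_population()] data frame (possibly zero rows).
#' @export
graduate_to_adults <- function(graduates, grid, id_start = 1L,
                               seed = NULL) {
  if (any(graduates < 0)) stop("graduate counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  idx <- which(graduates > 0)
  total <- sum(graduates[idx])
  if (total == 0) return(adult_population())
  csz <- grid$cell_size_m
  i <- (idx - 1L) %% nrow(graduates) + 1L     # row (y index)
  j <- (idx - 1L) %/% nrow(graduates) + 1L    # column (x index)
  reps <- graduates[idx]
  x0 <- rep((j - 1L) * csz, reps)
  y0 <- rep((i - 1L) * csz, reps)
  adult_population(
    id = seq.int(id_start, length.out = total),
    x = x0 + stats::runif(total, 0, csz),
    y = y0 + stats::runif(total, 0, csz),
    height = 3.0)
}
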