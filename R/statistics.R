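#' Standardize predictor columns
#'
#' Centres each column to mean zero and scales to unit SD so that
#' effect sizes are directly comparable across predictors. Constant
#' columns are rejected. The centring and scaling constants are kept as
#' attributes so the transform can be inverted.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @return Matrix with attributes \code{"center"} and \code{"scale"}.
#' @export
standardize_predictors <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant predictor columns cannot be standardized")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

# shared constructor for effect tables
new_effects_table <- function(coefs, se, dispersion, dev_expl, model) {
  est <- coefs
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    ci_lo = unname(est - 1.96 * se),
                    ci_hi = unname(est + 1.96 * se))
  structure(list(effects = tab, dispersion = dispersion,
                 deviance_explained = dev_expl, model = model),
            class = "effects_table")
}

#' @export
print.effects_table <- function(x, digits = 3, ...) {
  cat(sprintf("%s effects (95%% CIs):\n", x$model))
  tab <- x$effects
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-28s %8.*f (%.*f - %.*f)\n", tab$term[i],
                digits, tab$estimate[i], digits, tab$ci_lo[i],
                digits, tab$ci_hi[i]))
  cat(sprintf("  dispersion %.3f, deviance explained %.2f\n",
              x$dispersion, x$deviance_explained))
  invisible(x)
}

#' @export
coef.effects_table <- function(object, ...) {
  stats::setNames(object$effects$estimate, object$effects$term)
}

#' Overdispersed Poisson effect model
#'
#' Log-link Poisson regression of counts on predictors, fitted by
#' iteratively reweighted least squares, with standard errors inflated
#' by the square root of the Pearson dispersion (quasi-likelihood
#' correction for overdispersion). 95\% CIs are Wald intervals.
#'
#' @param y Non-negative integer counts.
#' @param X Predictor matrix (no intercept column; one is added).
#' @return An \code{"effects_table"}: per-term estimate, SE and CI,
#'   plus the dispersion and deviance explained
#'   (\code{1 - deviance/null deviance}). The fitted \code{glm} is kept
#'   in \code{$fit}.
#' @export
fit_poisson_overdispersed <- function(y, X) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be non-negative integer counts")
  X <- as.matrix(X)
  if (ncol(X) && qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("predictor matrix is rank deficient")
  if (ncol(X)) {
    df <- data.frame(y = y, X)
    fit <- stats::glm(y ~ ., data = df, family = stats::quasipoisson())
  } else {
    fit <- stats::glm(y ~ 1, family = stats::quasipoisson())
  }
  sm <- summary(fit)
  dev_expl <- if (fit$null.deviance <= 1e-12) 0 else
    1 - fit$deviance / fit$null.deviance
  out <- new_effects_table(stats::coef(fit), sm$coefficients[, "Std. Error"],
                           sm$dispersion, dev_expl,
                           "Overdispersed Poisson")
  out$fit <- fit
  out
}

#' Log-Gaussian effect model
#'
#' Ordinary least squares on the natural log of a positive response
#' (e.g. adult basal area), with the same Wald-CI convention as the
#' Poisson model; deviance explained is the R-squared.
#'
#' @param y Positive responses.
#' @param X Predictor matrix (no intercept column).
#' @return An \code{"effects_table"} (with \code{$fit} the \code{lm}).
#' @export
fit_gaussian_log <- function(y, X) {
  if (any(y <= 0)) stop("responses must be positive for the log transform")
  X <- as.matrix(X)
  df <- data.frame(logy = log(y), X)
  fit <- stats::lm(logy ~ ., data = df)
  sm <- summary(fit)
  out <- new_effects_table(stats::coef(fit), sm$coefficients[, "Std. Error"],
                           sm$sigma^2, sm$r.squared, "Log-Gaussian")
  out$fit <- fit
  out
}

#' Effect analysis of scenario-grid records
#'
#' Standardized-effect models of the simulation outputs on the four
#' experiment variables: mean deer browsing, mean substrate
#' favorability, initial adult density and the active-management
#' indicator (patch configuration). Juvenile counts use the
#' overdispersed Poisson model; basal area is log-transformed and
#' modelled as Gaussian.
#'
#' @param records A [run_scenario_grid()] record table (core and/or
#'   patch runs).
#' @param response \code{"n1"}, \code{"n2"} or \code{"ba"}.
#' @return An \code{"effects_table"}.
#' @export
analyze_effects <- function(records, response = c("n1", "n2", "ba")) {
  response <- match.arg(response)
  X <- cbind(browsing = records$mu_b,
             substrate = records$mu_s,
             density = records$density,
             management = as.numeric(records$configuration == "patch"))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  Xs <- standardize_predictors(X[, keep, drop = FALSE])
  switch(response,
         n1 = fit_poisson_overdispersed(records$n1_total, Xs),
         n2 = fit_poisson_overdispersed(records$n2_total, Xs),
         ba = fit_gaussian_log(records$adult_ba_m2, Xs))
}

#' Predicted-versus-observed validation
#'
#' Regresses median predicted counts on observed counts with an
#' overdispersed Poisson GLM and reports whether the slope and
#' intercept CIs cover 1 and 0, as expected for an unbiased model.
#'
#' @param median_predictions Per-plot median predicted counts.
#' @param observed Per-plot observed counts.
#' @return Object of class \code{"validation_report"}: intercept,
#'   slope, their 95\% CIs, deviance explained, coverage flags and the
#'   per-plot data.
#' @export
validate <- function(median_predictions, observed) {
  stopifnot(length(median_predictions) == length(observed))
  # identity link: the unbiasedness question is about the slope and
  # intercept on the count scale
  starts <- list(stats::coef(stats::lm(median_predictions ~ observed)),
                 c(max(mean(median_predictions), 0.1), 0),
                 c(0.1, 1))
  fit <- fallback <- NULL
  for (st in starts) {
    cand <- tryCatch(
      suppressWarnings(
        stats::glm(median_predictions ~ observed,
                   family = stats::quasipoisson(link = "identity"),
                   start = st)),
      error = function(e) NULL)
    if (is.null(cand)) next
    if (cand$converged) { fit <- cand; break }
    if (is.null(fallback)) fallback <- cand
  }
  if (is.null(fit)) fit <- fallback
  if (is.null(fit)) stop("validation GLM failed to converge")
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  tol <- 1e-8 * max(1, abs(est))
  structure(list(intercept = est[[1]], slope = est[[2]],
                 intercept_ci = ci[1, ], slope_ci = ci[2, ],
                 deviance_explained = if (fit$null.deviance <= 1e-12) 0 else
                   1 - fit$deviance / fit$null.deviance,
                 covers_unbiased = ci[2, 1] <= 1 + tol &&
                   ci[2, 2] >= 1 - tol &&
                   ci[1, 1] <= tol && ci[1, 2] >= -tol,
                 data = data.frame(observed = observed,
                                   predicted = median_predictions)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: y = %.2f + %.2f x; deviance explained %.0f%%\n",
              x$intercept, x$slope, 100 * x$deviance_explained))
  cat(sprintf("  intercept 95%% CI: %.2f - %.2f\n",
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  slope     95%% CI: %.2f - %.2f\n",
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  consistent with unbiased predictions: %s\n",
              if (x$covers_unbiased) "yes" else "no"))
  invisible(x)
}

#' Calibrate recruitment and survival multipliers
#'
#' Grid search over multiplier pairs applied to the potential-recruit
#' total (STR) and 0-2 m survival (s1). For each pair the supplied
#' validation harness produces a predicted-versus-observed fit; the
#' chosen pair minimizes the distance of the slope from 1,
#' tie-breaking on the intercept's distance from 0.
#'
#' @param harness Function of \code{(str_mult, s1_mult)} returning a
#'   \code{"validation_report"} (or any list with \code{slope} and
#'   \code{intercept}).
#' @param str_grid,s1_grid Candidate multipliers
#'   (default \code{seq(0.80, 1.10, 0.05)}).
#' @param tie_tol Slope-objective tolerance within which candidates are
#'   treated as tied (default 1e-8).
#' @return List with \code{str_mult}, \code{s1_mult} (chosen pair) and
#'   \code{surface}, the full objective table.
#' @export
calibrate_multipliers <- function(harness,
                                  str_grid = seq(0.80, 1.10, by = 0.05),
                                  s1_grid = seq(0.80, 1.10, by = 0.05),
                                  tie_tol = 1e-8) {
  surf <- expand.grid(str_mult = str_grid, s1_mult = s1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  surf$slope <- surf$intercept <- NA_real_
  for (i in seq_len(nrow(surf))) {
    rep_i <- harness(surf$str_mult[i], surf$s1_mult[i])
    surf$slope[i] <- rep_i$slope
    surf$intercept[i] <- rep_i$intercept
  }
  obj1 <- abs(surf$slope - 1)
  cand <- which(obj1 <= min(obj1) + tie_tol)
  best <- cand[which.min(abs(surf$intercept[cand]))]
  list(str_mult = surf$str_mult[best], s1_mult = surf$s1_mult[best],
       surface = surf)
}
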