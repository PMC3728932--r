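#' Adult tree population
#'
#' Individually tracked seed-bearing trees (height >= 3 m) with
#' continuous coordinates, stored as a plain data frame with columns
#' \code{id}, \code{x}, \code{y}, \code{height}.
#'
#' @param id Integer ids (unique).
#' @param x,y Positions in metres.
#' @param height Heights in metres (>= 3).
#' @return Data frame of class \code{c("adult_population", "data.frame")}.
#' @export
adult_population <- function(id = integer(0), x = numeric(0),
                             y = numeric(0), height = numeric(0)) {
  n <- max(length(id), length(x), length(y), length(height))
  if (n > 0 && length(height) && any(height < 3))
    stop("adult heights must be >= 3 m")
  df <- data.frame(id = as.integer(rep_len(id, n)),
                   x = rep_len(as.numeric(x), n),
                   y = rep_len(as.numeric(y), n),
                   height = rep_len(as.numeric(height), n))
  class(df) <- c("adult_population", "data.frame")
  df
}

#' @export
print.adult_population <- function(x, ...) {
  cat(sprintf("Adult population: %d trees", nrow(x)))
  if (nrow(x))
    cat(sprintf(", heights %.2f-%.2f m, basal area %.3f m2",
                min(x$height), max(x$height), basal_area(x)))
  cat("\n")
  invisible(x)
}

#' Adult demographic and allometric parameters
#'
#' Height growth declines exponentially with height,
#' \code{g(h) = a exp(-k h)}; the default coefficients solve the two
#' fitted anchors exactly (3-m trees grow 0.019 m/y, 25-m trees
#' 0.005 m/y). Background mortality is density-independent. Crown
#' radius and the height-diameter relation are simple documented
#' power-law assumptions: crown radius \code{= crown_radius_coef * h},
#' dbh \code{= hd_a * (h - 1.3)^hd_b} cm.
#'
#' @param growth_anchors Heights (m) and rates (m/y) pinning the growth
#'   curve; default \code{c(3, 25)} and \code{c(0.019, 0.005)}.
#' @param growth_rates Growth rates at the anchor heights.
#' @param mortality_m Annual death probability (default 0.025).
#' @param overtop_threshold Crown-overlap fraction at which an adult is
#'   removed (default 0.90).
#' @param crown_radius_coef Crown radius per metre of height
#'   (default 0.15).
#' @param hd_a,hd_b Height-to-dbh power-law coefficients (defaults 1
#'   and 1.25; dbh in cm, height in m above the 1.3-m breast height).
#' @return Object of class \code{"adult_params"} with derived
#'   \code{growth_a}, \code{growth_k}.
#' @export
adult_params <- function(growth_anchors = c(3, 25),
                         growth_rates = c(0.019, 0.005),
                         mortality_m = 0.025,
                         overtop_threshold = 0.90,
                         crown_radius_coef = 0.15,
                         hd_a = 1, hd_b = 1.25) {
  stopifnot(length(growth_anchors) == 2, length(growth_rates) == 2,
            all(growth_rates > 0), diff(growth_anchors) != 0,
            mortality_m >= 0, mortality_m <= 1)
  k <- log(growth_rates[1] / growth_rates[2]) / diff(growth_anchors)
  a <- growth_rates[1] * exp(k * growth_anchors[1])
  structure(list(growth_a = a, growth_k = k,
                 mortality_m = mortality_m,
                 overtop_threshold = overtop_threshold,
                 crown_radius_coef = crown_radius_coef,
                 hd_a = hd_a, hd_b = hd_b),
            class = "adult_params")
}

#' Adult height growth rate
#'
#' @param h Heights in metres (>= 3); vectorized.
#' @param params An \code{adult_params}.
#' @return Growth rates in m/y, \code{a exp(-k h)}.
#' @export
height_growth_rate <- function(h, params = adult_params()) {
  if (any(h < 3)) stop("adult heights must be >= 3 m")
  params$growth_a * exp(-params$growth_k * h)
}

#' Grow adults and apply background mortality
#'
#' Each adult dies independently with probability \code{mortality_m};
#' survivors grow by \code{g(h)} metres.
#'
#' @param pop An \code{adult_population}.
#' @param params An \code{adult_params}.
#' @param seed Optional integer seed.
#' @return Updated \code{adult_population} (dead trees removed).
#' @export
grow_and_kill_adults <- function(pop, params = adult_params(),
                                 seed = NULL) {
  if (!nrow(pop)) return(pop)
  if (!is.null(seed)) set.seed(seed)
  dead <- stats::runif(nrow(pop)) < params$mortality_m
  pop <- pop[!dead, , drop = FALSE]
  pop$height <- pop$height + height_growth_rate(pop$height, params)
  class(pop) <- c("adult_population", "data.frame")
  pop
}

#' Remove adults overtopped by taller neighbours
#'
#' An adult's crown is a disc of radius \code{crown_radius_coef * h}.
#' The overtopped fraction is the share of its crown area covered by
#' the union of crowns of strictly taller neighbours, computed by
#' rasterizing crowns on a fine subgrid; adults with fraction at or
#' above the threshold are removed, decided simultaneously from the
#' pre-removal population. Equal heights never overtop each other.
#'
#' @param pop An \code{adult_population}.
#' @param params An \code{adult_params}.
#' @param subgrid_m Rasterization resolution in metres (default 0.5).
#' @return Updated \code{adult_population}.
#' @export
overtopping_removal <- function(pop, params = adult_params(),
                                subgrid_m = 0.5) {
  if (nrow(pop) < 2) return(pop)
  frac <- overtop_fraction_cpp(pop$x, pop$y, pop$height,
                               params$crown_radius_coef, subgrid_m)
  keep <- frac < params$overtop_threshold
  pop <- pop[keep, , drop = FALSE]
  class(pop) <- c("adult_population", "data.frame")
  pop
}

#' Diameter at breast height from tree height
#'
#' Power-law allometry \code{dbh = hd_a * (h - 1.3)^hd_b} (cm); a
#' documented assumption, configurable through [adult_params()].
#'
#' @param h Heights in metres (> 1.3); vectorized.
#' @param params An \code{adult_params}.
#' @return Diameters in cm.
#' @export
dbh_from_height <- function(h, params = adult_params()) {
  if (any(h <= 1.3)) stop("heights must exceed breast height (1.3 m)")
  params$hd_a * (h - 1.3)^params$hd_b
}

#' Height from diameter at breast height
#'
#' Inverse of [dbh_from_height()].
#'
#' @param dbh Diameters in cm (> 0).
#' @param params An \code{adult_params}.
#' @return Heights in metres.
#' @export
height_from_dbh <- function(dbh, params = adult_params()) {
  if (any(dbh <= 0)) stop("dbh must be positive")
  1.3 + (dbh / params$hd_a)^(1 / params$hd_b)
}

#' Total basal area of an adult population
#'
#' @param pop An \code{adult_population}.
#' @param params An \code{adult_params}.
#' @return Basal area in m2: \code{sum(pi * (dbh/200)^2)}.
#' @export
basal_area <- function(pop, params = adult_params()) {
  if (!nrow(pop)) return(0)
  d <- dbh_from_height(pop$height, params)
  sum(pi * (d / 200)^2)
}

#' Read / write adult maps as CSV
#'
#' The on-disk schema is \code{id,x_m,y_m,height_m} (header required);
#' on export the derived columns \code{dbh_cm} and \code{crown_r_m} are
#' appended.
#'
#' @param path File path.
#' @return [read_adult_csv()]: an \code{adult_population}.
#' @export
read_adult_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("id", "x_m", "y_m", "height_m")
  if (!all(req %in% names(df)))
    stop("adult CSV must have columns id,x_m,y_m,height_m")
  adult_population(id = df$id, x = df$x_m, y = df$y_m,
                   height = df$height_m)
}

#' @rdname read_adult_csv
#' @param pop An \code{adult_population}.
#' @param params An \code{adult_params} (for the derived columns).
#' @export
write_adult_csv <- function(pop, path, params = adult_params()) {
  out <- data.frame(id = pop$id, x_m = pop$x, y_m = pop$y,
                    height_m = pop$height)
  if (nrow(pop)) {
    out$dbh_cm <- dbh_from_height(pop$height, params)
    out$crown_r_m <- params$crown_radius_coef * pop$height
  } else {
    out$dbh_cm <- numeric(0); out$crown_r_m <- numeric(0)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
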