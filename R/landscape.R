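#' Define the landscape grid
#'
#' The landscape is a regular grid of square cells, row-major with the
#' origin at the lower-left corner. Cell \code{(i, j)} (1-based row and
#' column) covers the half-open square
#' \code{[(j-1)c, jc) x [(i-1)c, ic)} in x and y, where \code{c} is the
#' cell size. Juvenile pools and substrate favorability are resolved at
#' this grid; adult trees carry continuous coordinates.
#'
#' @param width_m Landscape width in metres (> 0).
#' @param height_m Landscape height in metres (> 0).
#' @param cell_size_m Cell edge length in metres; must divide both
#'   dimensions exactly. Default 1 m, the resolution at which seedling
#'   recruitment is modelled.
#' @return An object of class \code{"grid_spec"} with elements
#'   \code{width_m}, \code{height_m}, \code{cell_size_m}, \code{ncol},
#'   \code{nrow}.
#' @export
grid_spec <- function(width_m, height_m = width_m, cell_size_m = 1) {
  stopifnot(is.finite(width_m), is.finite(height_m), is.finite(cell_size_m),
            width_m > 0, height_m > 0, cell_size_m > 0)
  nc <- width_m / cell_size_m
  nr <- height_m / cell_size_m
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("cell_size_m must divide width_m and height_m exactly")
  structure(list(width_m = width_m, height_m = height_m,
                 cell_size_m = cell_size_m,
                 ncol = as.integer(round(nc)), nrow = as.integer(round(nr))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Landscape grid: %g x %g m, %d x %d cells of %g m\n",
              x$width_m, x$height_m, x$nrow, x$ncol, x$cell_size_m))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A \code{grid_spec}.
#' @return List with vectors \code{x} (column centres) and \code{y}
#'   (row centres), in metres.
#' @export
cell_centers <- function(grid) {
  c_sz <- grid$cell_size_m
  list(x = (seq_len(grid$ncol) - 0.5) * c_sz,
       y = (seq_len(grid$nrow) - 0.5) * c_sz)
}

#' Sample from a truncated normal distribution
#'
#' Proper truncation by inversion of the conditional CDF: values are
#' distributed as Normal(mu, sd^2) conditioned on \code{[low, high]}.
#' Clipping draws to the bounds would pile probability mass onto the
#' endpoints and bias the extremes of scenario gradients, so it is not
#' used. With \code{sd = 0} the distribution is degenerate and the
#' function returns \code{mu} clamped into the interval.
#'
#' @param n Number of draws.
#' @param mu,sd Mean and standard deviation of the untruncated normal.
#' @param low,high Truncation bounds, \code{low < high}.
#' @param seed Optional integer seed (sets the RNG via [set.seed()]).
#' @return Numeric vector of length \code{n}, all values in
#'   \code{[low, high]}.
#' @export
rtruncnorm <- function(n, mu, sd, low = 0, high = 1, seed = NULL) {
  stopifnot(is.finite(mu), is.finite(sd), sd >= 0)
  if (!(low < high)) stop("low must be < high")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(min(max(mu, low), high), n))
  plo <- stats::pnorm(low, mu, sd)
  phi <- stats::pnorm(high, mu, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mu, sd)
  # qnorm can hit +/-Inf at u numerically 0 or 1 for extreme parameters
  pmin(pmax(x, low), high)
}

#' Moments of the truncated normal
#'
#' Closed-form mean and variance of Normal(mu, sd^2) truncated to
#' \code{[low, high]}; used as the analytic reference for the sampler.
#'
#' @inheritParams rtruncnorm
#' @return List with \code{mean} and \code{var}.
#' @export
truncnorm_moments <- function(mu, sd, low = 0, high = 1) {
  if (sd == 0) {
    m <- min(max(mu, low), high)
    return(list(mean = m, var = 0))
  }
  a <- (low - mu) / sd
  b <- (high - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

#' Draw a substrate-favorability field
#'
#' Per-cell ground-cover favorability for seedling establishment, drawn
#' i.i.d. from a truncated normal on [0, 1]. Favorability multiplies the
#' expected recruitment in each cell; 0 means no establishment possible,
#' 1 the best observed substrate (e.g. Agrostis-Festuca grassland).
#'
#' @param grid A \code{grid_spec}.
#' @param mu Mean of the untruncated normal, in [0, 1].
#' @param sd Standard deviation of the untruncated normal (default 0.13,
#'   paralleling the browsing process).
#' @param seed Optional integer seed.
#' @return Object of class \code{"substrate_field"}: a list with the
#'   grid, the favorability matrix (\code{nrow x ncol}, rows indexed from
#'   the lower-left), and the generating parameters.
#' @export
draw_substrate_field <- function(grid, mu, sd = 0.13, seed = NULL) {
  vals <- rtruncnorm(grid$nrow * grid$ncol, mu, sd, 0, 1, seed = seed)
  structure(list(grid = grid,
                 favorability = matrix(vals, grid$nrow, grid$ncol),
                 mu = mu, sd = sd),
            class = "substrate_field")
}

#' Draw an annual browsing series
#'
#' The exogenous deer-impact driver: the proportion of trees with
#' browse-damaged leader stems, drawn independently each year from a
#' truncated normal on [0, 1].
#'
#' @param mu Mean annual browsing proportion (untruncated scale).
#' @param sd Standard deviation (default 0.13, the interannual SD of
#'   observed browse damage).
#' @param years Number of years.
#' @param seed Optional integer seed.
#' @return Object of class \code{"browsing_process"}: list with
#'   \code{draws} (length-\code{years} vector in [0, 1]), \code{mu},
#'   \code{sd}.
#' @export
draw_browsing_series <- function(mu, sd = 0.13, years, seed = NULL) {
  b <- rtruncnorm(years, mu, sd, 0, 1, seed = seed)
  structure(list(draws = b, mu = mu, sd = sd), class = "browsing_process")
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Rows of the matrix are indexed from the lower-left (row 1 = south);
#' the ASCII format stores rows north-up, so row order is reversed on
#' write and restored on read.
#'
#' @param mat Numeric matrix.
#' @param path Output file path.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param cellsize Cell size in metres.
#' @param nodata NODATA sentinel value.
#' @export
write_esri_ascii <- function(mat, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  for (i in rev(seq_len(nrow(mat))))
    writeLines(paste(format(mat[i, ], digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with \code{mat} (rows indexed from the lower-left),
#'   \code{xllcorner}, \code{yllcorner}, \code{cellsize}, \code{nodata}.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]
  list(mat = m,
       xllcorner = hdr$xllcorner %||% 0, yllcorner = hdr$yllcorner %||% 0,
       cellsize = hdr$cellsize %||% 1, nodata = hdr$nodata_value %||% -9999)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
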