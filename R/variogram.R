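# great-circle distances in km between two coordinate sets
gcDistKm <- function(p1, p2 = NULL) {
  if (is.null(p2)) geosphere::distm(p1, fun = geosphere::distHaversine) / 1000
  else geosphere::distm(p1, p2, fun = geosphere::distHaversine) / 1000
}

# correlation part of the covariance model (1 at h = 0, -> 0 at large h)
variogramCorr <- function(family) {
  switch(family,
    exponential = function(h, range) exp(-h / range),
    gaussian    = function(h, range) exp(-(h / range)^2),
    spherical   = function(h, range) {
      u <- pmin(h / range, 1)
      1 - 1.5 * u + 0.5 * u^3
    },
    stop("unknown variogram family: ", family, call. = FALSE))
}

# semivariance gamma(h) for h > 0 under a fitted model
variogramModel <- function(h, vg) {
  corr <- variogramCorr(vg$family)
  ifelse(h == 0, 0, vg$nugget + vg$psill * (1 - corr(h, vg$range)))
}

#' Empirical semivariogram
#'
#' Bins the half squared differences of all point pairs by great-circle
#' distance.
#'
#' @param lon,lat,values point data
#' @param nBins number of equal-width distance bins
#' @param maxDist maximum pair distance used (km); default half the largest
#'   pair distance
#' @return data.frame with `dist` (bin mean distance), `gamma`, `n`
#' @export
empiricalVariogram <- function(lon, lat, values, nBins = 15, maxDist = NULL) {
  D <- gcDistKm(cbind(lon, lat))
  iu <- upper.tri(D)
  d <- D[iu]
  g <- 0.5 * outer(values, values, "-")[iu]^2
  if (is.null(maxDist)) maxDist <- max(d) / 2
  keep <- d <= maxDist & d > 0
  d <- d[keep]; g <- g[keep]
  bin <- pmin(floor(d / maxDist * nBins) + 1L, nBins)
  out <- data.frame(
    dist  = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    n     = as.integer(tapply(g, bin, length)))
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, partial sill and range to the empirical semivariogram by
#' minimizing the Cressie-weighted squared error
#' `sum(n_k * (gamma_k - model_k)^2 / model_k^2)` with box-constrained
#' quasi-Newton optimization from several starting points.
#'
#' @inheritParams empiricalVariogram
#' @param family `"exponential"` (default), `"spherical"` or `"gaussian"`
#' @return list with `family`, `nugget`, `psill`, `range` (km), `empirical`
#'   (the binned semivariogram) and `objective`
#' @export
fitVariogram <- function(lon, lat, values, family = c("exponential",
                         "spherical", "gaussian"), nBins = 15,
                         maxDist = NULL) {
  family <- match.arg(family)
  if (length(values) < 10)
    stop("need at least 10 points to fit a variogram", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate field: all values identical; a pure-nugget model ",
         "(or no interpolation) is the only sensible fallback", call. = FALSE)
  emp <- empiricalVariogram(lon, lat, values, nBins = nBins, maxDist = maxDist)
  if (nrow(emp) < 4)
    stop("too few occupied distance bins to fit a variogram", call. = FALSE)
  gmax <- max(emp$gamma); dmax <- max(emp$dist)
  obj <- function(p) {
    vg <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
    m <- variogramModel(emp$dist, vg)
    sum(emp$n * (emp$gamma - m)^2 / pmax(m, 1e-10)^2)
  }
  lower <- c(0, 1e-10, dmax / 200)
  upper <- c(2 * gmax, 4 * gmax, 4 * dmax)
  starts <- list(c(0.1 * gmax, 0.9 * gmax, dmax / 3),
                 c(0.5 * gmax, 0.5 * gmax, dmax / 10),
                 c(1e-6,       gmax,       dmax))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed to converge", call. = FALSE)
  list(family = family, nugget = best$par[1], psill = best$par[2],
       range = best$par[3], empirical = emp, objective = best$value)
}
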