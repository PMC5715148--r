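# average values at duplicated coordinates; kriging systems are singular
# otherwise
dedupCoords <- function(lon, lat, values) {
  key <- paste(sprintf("%.9f", lon), sprintf("%.9f", lat))
  if (!anyDuplicated(key))
    return(list(lon = lon, lat = lat, values = values, merged = 0L))
  v <- tapply(values, key, mean)
  first <- !duplicated(key)
  ord <- match(key[first], names(v))
  list(lon = lon[first], lat = lat[first], values = as.numeric(v[ord]),
       merged = sum(duplicated(key)))
}

#' Ordinary kriging prediction at arbitrary points
#'
#' Solves the ordinary-kriging system once for all prediction points under the
#' supplied variogram (covariance form `C(h) = psill * corr(h)`, `C(0) =
#' nugget + psill`) and returns the BLUP mean and kriging standard error.
#' Duplicate data coordinates are averaged first. The unbiasedness constraint
#' (weights summing to 1 at every prediction point) is asserted inside the
#' solver.
#'
#' @param lon,lat,values data points
#' @param predLon,predLat prediction locations
#' @param vg fitted variogram (list with `family`, `nugget`, `psill`, `range`)
#' @return list with `mean`, `se`, and `weights` (n x m matrix)
#' @export
krigePredict <- function(lon, lat, values, predLon, predLat, vg) {
  d <- dedupCoords(lon, lat, values)
  if (d$merged > 0)
    message(d$merged, " duplicate coordinate(s) averaged before kriging")
  n <- length(d$values)
  corr <- variogramCorr(vg$family)
  sill <- vg$nugget + vg$psill
  C <- vg$psill * corr(gcDistKm(cbind(d$lon, d$lat)), vg$range)
  diag(C) <- sill
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  C0 <- vg$psill * corr(gcDistKm(cbind(d$lon, d$lat),
                                 cbind(predLon, predLat)), vg$range)
  B <- rbind(C0, 1)
  W <- tryCatch(solve(A, B), error = function(e) {
    warning("near-singular kriging system; ridge added to the diagonal")
    A2 <- A
    diag(A2)[seq_len(n)] <- diag(A2)[seq_len(n)] + 1e-8 * sill
    solve(A2, B)
  })
  wts <- W[seq_len(n), , drop = FALSE]
  wsum <- colSums(wts)
  stopifnot("kriging weights must sum to 1" = all(abs(wsum - 1) < 1e-6))
  pred <- drop(crossprod(wts, d$values))
  s2 <- sill - colSums(wts * C0) - W[n + 1, ]
  list(mean = pred, se = sqrt(pmax(s2, 0)), weights = wts)
}

#' Fit an isoscape by ordinary kriging over a grid
#'
#' Predicts the chosen element at every ocean cell center of the grid, giving
#' a mean raster and a prediction-standard-error raster. The variogram is
#' fitted from the calibration points by [fitVariogram()] unless supplied.
#' Calibration samples must already be in epidermis currency (see
#' [toEpidermis()]).
#'
#' @param calibration calibration data.frame with `lon`, `lat` and the isotope
#'   columns
#' @param grid a [GridSpec-class]
#' @param element `"C"` or `"N"`
#' @param family variogram family, used when fitting
#' @param variogram optional pre-fitted variogram, bypassing the fit
#' @return an [Isoscape-class]
#' @export
krigeSurface <- function(calibration, grid, element = c("C", "N"),
                         family = "exponential", variogram = NULL) {
  element <- match.arg(element)
  vals <- calibration[[if (element == "C") "d13C" else "d15N"]]
  if ("tissue" %in% names(calibration) &&
      !all(calibration$tissue == "epidermis"))
    stop("calibration samples must be converted to epidermis currency first",
         call. = FALSE)
  idx <- cellIndexOf(grid, calibration$lon, calibration$lat)
  inside <- !is.na(idx[, "row"])
  if (sum(inside) < 10)
    stop("need at least 10 calibration points inside the grid", call. = FALSE)
  lon <- calibration$lon[inside]; lat <- calibration$lat[inside]
  vals <- vals[inside]
  vg <- if (is.null(variogram))
    fitVariogram(lon, lat, vals, family = family) else variogram
  cc <- cellCenters(grid)
  ocean <- as.vector(grid@mask)
  kr <- krigePredict(lon, lat, vals, cc[ocean, "lon"], cc[ocean, "lat"], vg)
  d <- gridDim(grid)
  mean <- se <- matrix(NA_real_, d[1], d[2])
  mean[ocean] <- kr$mean
  se[ocean] <- kr$se
  new("Isoscape", element = element, mean = mean, se = se, grid = grid,
      variogram = vg[c("family", "nugget", "psill", "range")])
}
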