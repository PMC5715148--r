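#' Pooled among-individual tissue covariance
#'
#' Computes the sample variance of d13C and d15N and their correlation within
#' each broad foraging area of the calibration set, then averages variances
#' and correlations across areas with equal weight. The pooled covariance is
#' re-implied as `r * sqrt(vC * vN)` (correlations, not raw covariances, are
#' averaged). Per-area matrices are kept for audit.
#'
#' @param calibration calibration data.frame with `area`, `d13C`, `d15N`
#' @param weighted average with per-area sample-size weights instead of
#'   equal weights
#' @param minPerArea minimum samples required per area
#' @return a [TissueCov-class]
#' @export
pooledTissueCovariance <- function(calibration, weighted = FALSE,
                                   minPerArea = 3L) {
  groups <- split(calibration, calibration$area)
  small <- names(groups)[vapply(groups, nrow, 0L) < minPerArea]
  if (length(small))
    stop("insufficient group(s) for tissue covariance (< ", minPerArea,
         " samples): ", paste(small, collapse = ", "), call. = FALSE)
  per <- lapply(groups, function(g)
    stats::cov(cbind(d13C = g$d13C, d15N = g$d15N)))
  vC <- vapply(per, function(m) m[1, 1], 0)
  vN <- vapply(per, function(m) m[2, 2], 0)
  r  <- vapply(per, function(m) m[1, 2] / sqrt(m[1, 1] * m[2, 2]), 0)
  if (any(!is.finite(r)))
    stop("zero within-area variance; correlation undefined", call. = FALSE)
  w <- if (weighted) vapply(groups, nrow, 0L) else rep(1, length(groups))
  w <- w / sum(w)
  mvC <- sum(w * vC); mvN <- sum(w * vN); mr <- sum(w * r)
  new("TissueCov", vC = mvC, vN = mvN, r = mr,
      cov = mr * sqrt(mvC * mvN), perArea = per)
}

#' Assemble the per-cell covariance field
#'
#' At each ocean cell the bivariate error covariance is the pooled tissue
#' matrix plus the squared kriging standard errors on the diagonal (variances
#' add under the assumed independence of tissue variation and interpolation
#' error); the off-diagonal is the tissue covariance, since the kriging model
#' provides only univariate errors. A ridge is added to the diagonal in the
#' (theoretically impossible for |r| < 1) event a cell matrix is not positive
#' definite.
#'
#' @param tissue a [TissueCov-class]
#' @param isoC,isoN the carbon and nitrogen [Isoscape-class]s (shared grid)
#' @param ridge diagonal safety ridge
#' @return a [CovField-class]
#' @export
buildCovField <- function(tissue, isoC, isoN, ridge = 1e-8) {
  if (!sameGrid(isoC@grid, isoN@grid))
    stop("isoscapes must share the same grid", call. = FALSE)
  varC <- tissue@vC + isoC@se^2
  varN <- tissue@vN + isoN@se^2
  m <- isoC@grid@mask
  det <- varC[m] * varN[m] - tissue@cov^2
  if (any(det <= 0, na.rm = TRUE)) {
    warning("non-positive-definite cell covariance; ridge applied")
    varC[m] <- varC[m] + ridge
    varN[m] <- varN[m] + ridge
  }
  new("CovField", grid = isoC@grid, varC = varC, varN = varN,
      covCN = tissue@cov)
}

#' Bivariate normal density
#'
#' Direct closed form for a single 2-vector; used as the per-cell error model
#' of the assignment step.
#'
#' @param x length-2 observation (d13C, d15N)
#' @param mu length-2 mean
#' @param sigma 2x2 positive-definite covariance
#' @param log return the log density
#' @return the (log) density
#' @examples
#' bivariateDensity(c(0, 0), c(0, 0), diag(2))  # 1 / (2 * pi)
#' @export
bivariateDensity <- function(x, mu, sigma, log = FALSE) {
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (!is.finite(det) || det <= 0)
    stop("sigma must be positive definite", call. = FALSE)
  d <- x - mu
  q <- (sigma[2, 2] * d[1]^2 - 2 * sigma[1, 2] * d[1] * d[2] +
          sigma[1, 1] * d[2]^2) / det
  ld <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  if (log) ld else exp(ld)
}

# log bivariate-normal density of one sample against every ocean cell,
# returned as a flattened vector (NA off-mask); all arithmetic in log space
logDensityCells <- function(xC, xN, isoC, isoN, cov) {
  m <- cov@grid@mask
  dC <- xC - isoC@mean[m]
  dN <- xN - isoN@mean[m]
  a <- cov@varC[m]; c <- cov@varN[m]; b <- cov@covCN
  det <- a * c - b^2
  q <- (c * dC^2 - 2 * b * dC * dN + a * dN^2) / det
  ll <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  out <- rep(NA_real_, length(m))
  out[as.vector(m)] <- ll
  out
}

#' Normalized posterior assignment surface for one individual
#'
#' Evaluates the bivariate-normal density of the individual's isotope values
#' at every ocean cell (cell mean from the isoscapes, cell covariance from the
#' covariance field) and rescales by the raster maximum, so the most probable
#' foraging cell(s) carry exactly 1. Computation is done in log space and the
#' maximum subtracted before exponentiating, so distant cells underflow to 0
#' gracefully rather than zeroing the whole raster.
#'
#' @param sample one-row data.frame in epidermis currency
#' @param isoC,isoN the element [Isoscape-class]s
#' @param cov a [CovField-class]
#' @return an [AssignmentSurface-class]
#' @export
assignmentSurface <- function(sample, isoC, isoN, cov) {
  stack <- assignSamples(sample, isoC, isoN, cov)
  stack[[1L]]
}

#' Assignment surfaces for a cohort
#'
#' Vectorized version of [assignmentSurface()]; returns all surfaces in a
#' [SurfaceStack-class] sharing the grid.
#'
#' @param samples data.frame of individuals in epidermis currency
#' @inheritParams assignmentSurface
#' @return a [SurfaceStack-class]
#' @export
assignSamples <- function(samples, isoC, isoN, cov) {
  if (!sameGrid(isoC@grid, cov@grid) || !sameGrid(isoN@grid, cov@grid))
    stop("isoscapes and covariance field must share the grid", call. = FALSE)
  if ("tissue" %in% names(samples) && !all(samples$tissue == "epidermis"))
    stop("samples must be converted to epidermis currency first; ",
         "see toEpidermis()", call. = FALSE)
  n <- nrow(samples)
  vals <- matrix(NA_real_, length(cov@grid@mask), n)
  for (j in seq_len(n)) {
    ll <- logDensityCells(samples$d13C[j], samples$d15N[j], isoC, isoN, cov)
    top <- max(ll, na.rm = TRUE)
    if (!is.finite(top))
      stop("assignment underflow for id ", samples$id[j],
           ": no finite cell density", call. = FALSE)
    vals[, j] <- exp(ll - top)
  }
  years <- if ("year" %in% names(samples)) as.integer(samples$year)
           else rep(NA_integer_, n)
  new("SurfaceStack", grid = cov@grid, ids = as.character(samples$id),
      years = years, values = vals)
}

#' Validate assignment against known-origin individuals
#'
#' Looks up each calibration individual's normalized surface value at its true
#' foraging cell (snapping to the nearest ocean cell within `snapCells` when
#' the coordinates resolve to a masked-out pixel) and summarizes the
#' distribution. High medians mean the continuous-surface model concentrates
#' probability near the true origins.
#'
#' @param stack [SurfaceStack-class] of calibration surfaces
#' @param calibration the matching calibration data.frame (`id`, `lon`, `lat`)
#' @param snapCells snap tolerance in cells
#' @return list with `values` (named per individual), `median`, `q1`
#' @export
validateCalibration <- function(stack, calibration, snapCells = 1L) {
  i <- match(calibration$id, stack@ids)
  if (any(is.na(i)))
    stop("calibration ids missing from the surface stack", call. = FALSE)
  grid <- stack@grid
  idx <- cellIndexOf(grid, calibration$lon, calibration$lat)
  vals <- vapply(seq_len(nrow(calibration)), function(k) {
    if (is.na(idx[k, "row"]))
      stop("calibration location outside the grid for id ",
           calibration$id[k], call. = FALSE)
    rc <- snapToOcean(grid, idx[k, "row"], idx[k, "col"], maxCells = snapCells)
    stack@values[flatIndex(grid, rc["row"], rc["col"]), i[k]]
  }, 0)
  names(vals) <- calibration$id
  list(values = vals,
       median = stats::median(vals),
       q1 = unname(stats::quantile(vals, 0.25)))
}
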