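#' Foraging-importance index
#'
#' Cell-wise sum of the normalized assignment surfaces of a cohort, optionally
#' restricted to one nesting year. The sum is a probability-weighted index of
#' the evidence that a cell was used — the probable number of individuals that
#' used the cell, not a count of individuals.
#'
#' @param stack a [SurfaceStack-class]
#' @param year optional year filter
#' @return an [ImportanceIndex-class] with `weighting = "count"`
#' @export
foragingIndex <- function(stack, year = NULL) {
  sel <- if (is.null(year)) seq_along(stack@ids)
         else which(stack@years == year)
  if (length(sel) == 0)
    stop("empty cohort: no surfaces", if (!is.null(year))
      paste0(" for year ", year), call. = FALSE)
  v <- rowSums(stack@values[, sel, drop = FALSE])
  new("ImportanceIndex", grid = stack@grid,
      values = matrix(v, gridDim(stack@grid)[1]),
      year = if (is.null(year)) "overall" else as.character(year),
      weighting = "count", n = length(sel), totalWeight = length(sel))
}

#' Reproduction-weighted importance index
#'
#' Cell-wise sum of each individual's surface multiplied by its reproductive
#' weight (clutch size in eggs, or emergents). Individuals with a missing
#' weight are excluded with a warning, mirroring the restriction to nests with
#' recorded fate.
#'
#' @param stack a [SurfaceStack-class]
#' @param weights numeric weights named by individual id
#' @param year optional year filter
#' @param weighting `"eggs"` or `"emergents"` (label only)
#' @return an [ImportanceIndex-class]
#' @export
weightedIndex <- function(stack, weights, year = NULL,
                          weighting = c("eggs", "emergents")) {
  weighting <- match.arg(weighting)
  sel <- if (is.null(year)) seq_along(stack@ids)
         else which(stack@years == year)
  if (length(sel) == 0)
    stop("empty cohort: no surfaces", call. = FALSE)
  w <- weights[stack@ids[sel]]
  drop <- is.na(w)
  if (any(drop)) {
    warning(sum(drop), " individual(s) without a recorded ", weighting,
            " weight excluded")
    sel <- sel[!drop]; w <- w[!drop]
  }
  if (length(sel) == 0)
    stop("empty cohort: no individuals with recorded weights", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  # scale columns then rowSums: with unit weights this reproduces the
  # unweighted index bit-for-bit (same summation order as foragingIndex)
  sub <- stack@values[, sel, drop = FALSE]
  v <- rowSums(sub * rep(w, each = nrow(sub)))
  new("ImportanceIndex", grid = stack@grid,
      values = matrix(v, gridDim(stack@grid)[1]),
      year = if (is.null(year)) "overall" else as.character(year),
      weighting = weighting, n = length(sel), totalWeight = sum(w))
}

#' Emergence-success rate surface
#'
#' Cell-wise ratio of the emergent-weighted to the egg-weighted importance
#' index of the same cohort: the probability-weighted mean per-nest emergence
#' rate at each cell. Cells with zero egg index are `NA`.
#'
#' @param eggIndex,emergentIndex matching [ImportanceIndex-class]es
#' @return a [RateSurface-class]
#' @export
emergenceRateSurface <- function(eggIndex, emergentIndex) {
  if (!sameGrid(eggIndex@grid, emergentIndex@grid))
    stop("indices must share the grid", call. = FALSE)
  if (eggIndex@year != emergentIndex@year ||
      eggIndex@n != emergentIndex@n)
    stop("indices must describe the same cohort and year", call. = FALSE)
  v <- emergentIndex@values / eggIndex@values
  v[!is.na(eggIndex@values) & eggIndex@values == 0] <- NA_real_
  new("RateSurface", grid = eggIndex@grid, values = v,
      year = eggIndex@year, n = eggIndex@n)
}

#' Which grid cells belong to each hotspot
#'
#' Membership is decided by cell center inside the polygon (even-odd rule via
#' `mgcv::in.out`), which is deterministic under vertex ordering.
#'
#' @param hotspots a [HotspotSet-class]
#' @param grid a [GridSpec-class]
#' @return named list of flattened logical cell-membership vectors
#' @export
hotspotCellMembership <- function(hotspots, grid) {
  cc <- cellCenters(grid)
  out <- lapply(seq_along(hotspots@names), function(i) {
    inside <- mgcv::in.out(hotspots@polygons[[i]], cc) & as.vector(grid@mask)
    if (!any(inside))
      stop("empty hotspot: polygon '", hotspots@names[i],
           "' covers no ocean cell center", call. = FALSE)
    inside
  })
  names(out) <- hotspots@names
  out
}

#' Hotspot-by-year contribution table
#'
#' For each year's importance index, sums the index over the cells of each
#' hotspot polygon, then normalizes: `by_n` divides each year column by that
#' year's number of contributing individuals (the annual map convention);
#' `by_hotspot_total` rescales each year column to sum to 1 across hotspots
#' (relative contributions); `none` leaves raw sums.
#'
#' @param indices named list of per-year [ImportanceIndex-class]es (names are
#'   year labels)
#' @param hotspots a [HotspotSet-class]
#' @param normalize `"by_n"`, `"by_hotspot_total"` or `"none"`
#' @return a [ContributionTable-class]
#' @export
hotspotTable <- function(indices, hotspots,
                         normalize = c("by_n", "by_hotspot_total", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(indices) >= 1)
  grid <- indices[[1]]@grid
  members <- hotspotCellMembership(hotspots, grid)
  vals <- vapply(indices, function(idx) {
    if (!sameGrid(idx@grid, grid)) stop("indices must share the grid")
    v <- as.vector(idx@values)
    vapply(members, function(m) sum(v[m]), 0)
  }, numeric(length(members)))
  vals <- matrix(vals, nrow = length(members),
                 dimnames = list(hotspots@names,
                                 if (is.null(names(indices)))
                                   vapply(indices, function(i) i@year, "")
                                 else names(indices)))
  n <- vapply(indices, function(i) i@n, 0L)
  if (normalize == "by_n") vals <- sweep(vals, 2, n, "/")
  if (normalize == "by_hotspot_total") {
    tot <- colSums(vals)
    if (any(tot == 0)) stop("a year column sums to zero", call. = FALSE)
    vals <- sweep(vals, 2, tot, "/")
  }
  metric <- switch(indices[[1]]@weighting, count = "female_index",
                   eggs = "egg_index", emergents = "emergent_index")
  new("ContributionTable", values = vals, metric = metric,
      normalization = normalize, nPerYear = n)
}

#' Hotspot-by-year emergence-rate table
#'
#' Per hotspot and year, the ratio of the zonal sums of the emergent- and
#' egg-weighted indices — the egg-weighted mean emergence rate of the nests
#' whose assignment mass falls in the hotspot. Entries lie in \[0, 1\].
#'
#' @param eggIndices,emergentIndices named per-year lists of matching
#'   [ImportanceIndex-class]es
#' @param hotspots a [HotspotSet-class]
#' @return a [ContributionTable-class] with metric `"emergence_rate"`
#' @export
emergenceRateTable <- function(eggIndices, emergentIndices, hotspots) {
  stopifnot(length(eggIndices) == length(emergentIndices))
  grid <- eggIndices[[1]]@grid
  members <- hotspotCellMembership(hotspots, grid)
  years <- names(eggIndices)
  vals <- sapply(seq_along(eggIndices), function(y) {
    egg <- as.vector(eggIndices[[y]]@values)
    eme <- as.vector(emergentIndices[[y]]@values)
    vapply(members, function(m) {
      denom <- sum(egg[m])
      if (denom == 0) NA_real_ else sum(eme[m]) / denom
    }, 0)
  })
  vals <- matrix(vals, nrow = length(members),
                 dimnames = list(hotspots@names, years))
  new("ContributionTable", values = vals, metric = "emergence_rate",
      normalization = "none",
      nPerYear = vapply(eggIndices, function(i) i@n, 0L))
}
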