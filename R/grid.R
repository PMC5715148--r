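#' Construct a GridSpec
#'
#' @param lonMin,lonMax,latMin,latMax bounding box in decimal degrees
#' @param cellSize cell edge in degrees
#' @param crs coordinate reference system identifier
#' @param mask optional logical `nLat x nLon` matrix; default all ocean
#' @return a [GridSpec-class]
#' @examples
#' g <- gridSpec(-85, -60, 23, 45, 0.5)
#' gridDim(g)
#' @export
gridSpec <- function(lonMin, lonMax, latMin, latMax, cellSize,
                     crs = "EPSG:4326", mask = NULL) {
  nlon <- round((lonMax - lonMin) / cellSize)
  nlat <- round((latMax - latMin) / cellSize)
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  new("GridSpec", lonMin = lonMin, lonMax = lonMax, latMin = latMin,
      latMax = latMax, cellSize = cellSize, crs = crs, mask = mask)
}

#' Grid dimensions
#' @param grid a [GridSpec-class]
#' @return integer `c(nLat, nLon)`
#' @export
gridDim <- function(grid) dim(grid@mask)

#' Cell-center coordinates
#'
#' `lonCenters`/`latCenters` give the axis center coordinates;
#' `cellCenters` returns all centers in flattened (column-major) cell order.
#'
#' @param grid a [GridSpec-class]
#' @return numeric vector, or a two-column `lon`/`lat` matrix
#' @export
lonCenters <- function(grid)
  grid@lonMin + (seq_len(gridDim(grid)[2]) - 0.5) * grid@cellSize

#' @rdname lonCenters
#' @export
latCenters <- function(grid)
  grid@latMin + (seq_len(gridDim(grid)[1]) - 0.5) * grid@cellSize

#' @rdname lonCenters
#' @export
cellCenters <- function(grid) {
  d <- gridDim(grid)
  cbind(lon = rep(lonCenters(grid), each = d[1]),
        lat = rep(latCenters(grid), times = d[2]))
}

#' Locate points on the grid
#'
#' Maps coordinates to `(row, col)` cell indices; points outside the bounding
#' box get `NA`.
#'
#' @param grid a [GridSpec-class]
#' @param lon,lat point coordinates
#' @return integer matrix with columns `row`, `col`
#' @export
cellIndexOf <- function(grid, lon, lat) {
  d <- gridDim(grid)
  col <- floor((lon - grid@lonMin) / grid@cellSize) + 1L
  row <- floor((lat - grid@latMin) / grid@cellSize) + 1L
  # points exactly on the max edge belong to the last cell
  col[lon == grid@lonMax] <- d[2]
  row[lat == grid@latMax] <- d[1]
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1] |
    is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Snap a cell to the nearest ocean cell
#'
#' Coastal capture coordinates often resolve to land pixels; this searches a
#' Chebyshev neighbourhood of `maxCells` around the target and returns the
#' nearest masked-in cell by center distance, or errors when none exists.
#'
#' @param grid a [GridSpec-class]
#' @param row,col target cell
#' @param maxCells search radius in cells (default 1)
#' @return integer `c(row, col)` of an ocean cell
#' @export
snapToOcean <- function(grid, row, col, maxCells = 1L) {
  d <- gridDim(grid)
  row <- unname(row); col <- unname(col)
  if (is.na(row) || is.na(col))
    stop("cell indices are NA; point lies outside the grid", call. = FALSE)
  if (grid@mask[row, col]) return(c(row = row, col = col))
  rows <- max(1L, row - maxCells):min(d[1], row + maxCells)
  cols <- max(1L, col - maxCells):min(d[2], col + maxCells)
  cand <- expand.grid(row = rows, col = cols)
  cand <- cand[grid@mask[as.matrix(cand)], , drop = FALSE]
  if (nrow(cand) == 0)
    stop(sprintf("no ocean cell within %d cell(s) of (%d, %d)",
                 maxCells, row, col), call. = FALSE)
  dist2 <- (cand$row - row)^2 + (cand$col - col)^2
  best <- cand[which.min(dist2), ]
  c(row = best$row, col = best$col)
}

# column-major flat index of (row, col) cells
flatIndex <- function(grid, row, col) row + (col - 1L) * gridDim(grid)[1]

# bilinear interpolation of a grid raster at arbitrary points; points are
# clamped to the span of the cell centers so edge cells extrapolate flat
interpBilinear <- function(grid, values, lon, lat) {
  lc <- lonCenters(grid); la <- latCenters(grid)
  x <- pmin(pmax(lon, lc[1]), lc[length(lc)])
  y <- pmin(pmax(lat, la[1]), la[length(la)])
  j <- pmin(pmax(findInterval(x, lc), 1L), length(lc) - 1L)
  i <- pmin(pmax(findInterval(y, la), 1L), length(la) - 1L)
  tx <- (x - lc[j]) / grid@cellSize
  ty <- (y - la[i]) / grid@cellSize
  v00 <- values[cbind(i, j)];     v01 <- values[cbind(i, j + 1L)]
  v10 <- values[cbind(i + 1L, j)]; v11 <- values[cbind(i + 1L, j + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' @export
setMethod("show", "GridSpec", function(object) {
  d <- gridDim(object)
  cat(sprintf("GridSpec: %d x %d cells of %.3g deg, lon [%g, %g], lat [%g, %g] (%s)\n",
              d[1], d[2], object@cellSize, object@lonMin, object@lonMax,
              object@latMin, object@latMax, object@crs))
  cat(sprintf("  ocean cells: %d of %d\n", sum(object@mask), length(object@mask)))
})

#' @export
setMethod("show", "Isoscape", function(object) {
  vg <- object@variogram
  cat(sprintf("Isoscape d%s: mean in [%.2f, %.2f], se in [%.3f, %.3f]\n",
              if (object@element == "C") "13C" else "15N",
              min(object@mean, na.rm = TRUE), max(object@mean, na.rm = TRUE),
              min(object@se, na.rm = TRUE), max(object@se, na.rm = TRUE)))
  cat(sprintf("  variogram: %s (nugget %.3g, psill %.3g, range %.3g km)\n",
              vg$family, vg$nugget, vg$psill, vg$range))
})

#' @export
setMethod("show", "AssignmentSurface", function(object) {
  cat(sprintf("AssignmentSurface %s (year %d): max 1 at %d cell(s)\n",
              object@id, object@year,
              sum(object@values == 1, na.rm = TRUE)))
})

#' @export
setMethod("show", "SurfaceStack", function(object) {
  cat(sprintf("SurfaceStack: %d surfaces on a %s grid, years %s\n",
              length(object@ids), paste(gridDim(object@grid), collapse = " x "),
              paste(range(object@years), collapse = "-")))
})

#' @export
setMethod("show", "ImportanceIndex", function(object) {
  cat(sprintf("ImportanceIndex (%s, %s): n = %d, total weight %.6g, cell max %.4g\n",
              object@weighting, object@year, object@n, object@totalWeight,
              max(object@values, na.rm = TRUE)))
})

#' @export
setMethod("show", "ContributionTable", function(object) {
  cat(sprintf("ContributionTable (%s, %s):\n", object@metric,
              object@normalization))
  print(round(object@values, 4))
})

#' @export
setMethod("show", "FriedmanResult", function(object) {
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p = %.4g\n",
              object@statistic, object@df, object@p.value))
  if (!is.na(object@p.exact))
    cat(sprintf("  exact permutation p = %.4g\n", object@p.exact))
})

#' @export
setMethod("show", "TissueCov", function(object) {
  cat(sprintf("TissueCov: vC = %.4g, vN = %.4g, r = %.4g (cov %.4g) from %d areas\n",
              object@vC, object@vN, object@r, object@cov,
              length(object@perArea)))
})

#' Extract one surface from a stack
#' @param x a [SurfaceStack-class]
#' @param i index or id
#' @export
setMethod("[[", "SurfaceStack", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  new("AssignmentSurface", id = x@ids[i], year = x@years[i],
      values = matrix(x@values[, i], gridDim(x@grid)[1]), grid = x@grid)
})

#' Accessors
#'
#' `gridSpecOf` returns the grid attached to a spatial object; `rasterValues`
#' returns its value matrix.
#'
#' @param x an isoforage spatial object
#' @export
setGeneric("gridSpecOf", function(x) standardGeneric("gridSpecOf"))
#' @rdname gridSpecOf
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname gridSpecOf
setMethod("gridSpecOf", "Isoscape", function(x) x@grid)
#' @rdname gridSpecOf
setMethod("gridSpecOf", "CovField", function(x) x@grid)
#' @rdname gridSpecOf
setMethod("gridSpecOf", "AssignmentSurface", function(x) x@grid)
#' @rdname gridSpecOf
setMethod("gridSpecOf", "SurfaceStack", function(x) x@grid)
#' @rdname gridSpecOf
setMethod("gridSpecOf", "ImportanceIndex", function(x) x@grid)
#' @rdname gridSpecOf
setMethod("gridSpecOf", "RateSurface", function(x) x@grid)

#' @rdname gridSpecOf
setMethod("rasterValues", "AssignmentSurface", function(x) x@values)
#' @rdname gridSpecOf
setMethod("rasterValues", "ImportanceIndex", function(x) x@values)
#' @rdname gridSpecOf
setMethod("rasterValues", "RateSurface", function(x) x@values)

sameGrid <- function(a, b) {
  isTRUE(all.equal(c(a@lonMin, a@lonMax, a@latMin, a@latMax, a@cellSize),
                   c(b@lonMin, b@lonMax, b@latMin, b@latMax, b@cellSize))) &&
    identical(a@mask, b@mask)
}
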