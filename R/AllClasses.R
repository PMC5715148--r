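#' @import methods
NULL

TISSUES <- c("epidermis", "red_blood_cells", "unhatched_egg")
CAL_AREAS <- c("CAN", "MAB", "SAB", "SNWA", "FLKeys", "SWFL")
HOTSPOT_NAMES <- c("N_Hatteras", "S_Hatteras", "SC_GA", "E_FL",
                   "Bahamas", "FL_Keys", "W_FL")

#' Regular longitude/latitude analysis grid with an ocean mask
#'
#' A `GridSpec` defines the raster geometry shared by all surfaces in an
#' analysis: a geographic bounding box, a square cell size in decimal degrees,
#' and a logical ocean mask (`TRUE` = usable cell). Raster values are stored
#' as matrices with rows indexing latitude (ascending from `latMin`) and
#' columns indexing longitude (ascending from `lonMin`); flattened cell order
#' is column-major, matching `as.vector()` on such a matrix.
#'
#' @slot lonMin,lonMax,latMin,latMax bounding box, decimal degrees
#' @slot cellSize cell edge in degrees (> 0)
#' @slot crs coordinate reference system identifier (informational)
#' @slot mask logical matrix, `nLat x nLon`; `TRUE` marks ocean (usable) cells
#' @export
setClass("GridSpec",
  representation(lonMin = "numeric", lonMax = "numeric",
                 latMin = "numeric", latMax = "numeric",
                 cellSize = "numeric", crs = "character", mask = "matrix"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@lonMax <= object@lonMin || object@latMax <= object@latMin)
    msg <- c(msg, "bounding box is empty")
  nlon <- round((object@lonMax - object@lonMin) / object@cellSize)
  nlat <- round((object@latMax - object@latMin) / object@cellSize)
  if (abs(nlon * object@cellSize - (object@lonMax - object@lonMin)) > 1e-8 ||
      abs(nlat * object@cellSize - (object@latMax - object@latMin)) > 1e-8)
    msg <- c(msg, "bounding box spans must be integer multiples of cellSize")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  else if (!all(dim(object@mask) == c(nlat, nlon)))
    msg <- c(msg, sprintf("mask must be %d x %d to match the grid", nlat, nlon))
  if (length(msg)) msg else TRUE
})

#' Fitted isotope prediction surface (mean + standard error)
#'
#' Paired rasters of kriged isotope predictions and their prediction standard
#' errors for one element, plus the fitted variogram parameters. Masked-out
#' cells are `NA` in both rasters.
#'
#' @slot element `"C"` or `"N"`
#' @slot mean,se numeric matrices on the grid (per-mil; se >= 0 on ocean cells)
#' @slot grid the shared [GridSpec-class]
#' @slot variogram list with `family`, `nugget`, `psill`, `range` (km)
#' @export
setClass("Isoscape",
  representation(element = "character", mean = "matrix", se = "matrix",
                 grid = "GridSpec", variogram = "list"))

setValidity("Isoscape", function(object) {
  msg <- character()
  if (!object@element %in% c("C", "N"))
    msg <- c(msg, "element must be 'C' or 'N'")
  dm <- dim(object@grid@mask)
  if (!all(dim(object@mean) == dm) || !all(dim(object@se) == dm))
    msg <- c(msg, "mean/se rasters must match the grid dimensions")
  else {
    m <- object@grid@mask
    if (any(!is.finite(object@se[m])) || any(object@se[m] < 0))
      msg <- c(msg, "se must be finite and non-negative on ocean cells")
    if (any(!is.na(object@mean[!m])) || any(!is.na(object@se[!m])))
      msg <- c(msg, "masked-out cells must be NA")
  }
  if (length(msg)) msg else TRUE
})

#' Pooled among-individual tissue covariance
#'
#' Mean among-individual variances of d13C and d15N and the mean correlation
#' across the broad calibration foraging areas, with the implied covariance
#' `cov = r * sqrt(vC * vN)`. Per-area component matrices are retained for
#' audit.
#'
#' @slot vC,vN mean among-individual variances (per-mil squared)
#' @slot r mean among-individual correlation, in \[-1, 1\]
#' @slot cov implied covariance
#' @slot perArea named list of per-area 2x2 sample covariance matrices
#' @export
setClass("TissueCov",
  representation(vC = "numeric", vN = "numeric", r = "numeric",
                 cov = "numeric", perArea = "list"))

setValidity("TissueCov", function(object) {
  msg <- character()
  if (object@vC <= 0 || object@vN <= 0)
    msg <- c(msg, "variances must be positive")
  if (abs(object@r) > 1) msg <- c(msg, "correlation must lie in [-1, 1]")
  if (abs(object@cov - object@r * sqrt(object@vC * object@vN)) > 1e-8)
    msg <- c(msg, "cov must equal r * sqrt(vC * vN)")
  if (length(msg)) msg else TRUE
})

#' Per-cell 2x2 covariance field for the bivariate assignment model
#'
#' Diagonal entries are the pooled tissue variances plus the squared kriging
#' standard errors of the corresponding cell; the off-diagonal is the (cell
#' constant) pooled tissue covariance.
#'
#' @slot grid the shared [GridSpec-class]
#' @slot varC,varN per-cell variance rasters
#' @slot covCN scalar off-diagonal covariance
#' @export
setClass("CovField",
  representation(grid = "GridSpec", varC = "matrix", varN = "matrix",
                 covCN = "numeric"))

setValidity("CovField", function(object) {
  m <- object@grid@mask
  if (!all(dim(object@varC) == dim(m)) || !all(dim(object@varN) == dim(m)))
    return("variance rasters must match the grid")
  det <- object@varC[m] * object@varN[m] - object@covCN^2
  if (any(!is.finite(det)) || any(det <= 0))
    return("every per-cell covariance matrix must be positive definite")
  TRUE
})

#' Normalized posterior assignment surface for one individual
#'
#' Raster of bivariate-normal posterior values rescaled by the raster maximum,
#' so the most probable foraging cell(s) carry exactly 1 and all ocean cells
#' lie in \[0, 1\].
#'
#' @slot id individual identifier
#' @slot year nesting season
#' @slot values normalized raster (masked-out cells `NA`)
#' @slot grid the shared [GridSpec-class]
#' @export
setClass("AssignmentSurface",
  representation(id = "character", year = "integer", values = "matrix",
                 grid = "GridSpec"))

setValidity("AssignmentSurface", function(object) {
  m <- object@grid@mask
  v <- object@values[m]
  if (!all(dim(object@values) == dim(m)))
    return("values must match the grid dimensions")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("ocean-cell values must be finite and in [0, 1]")
  if (max(v) != 1) return("the raster maximum must be exactly 1")
  if (any(!is.na(object@values[!m]))) return("masked-out cells must be NA")
  TRUE
})

#' Stack of assignment surfaces sharing one grid
#'
#' Column `j` of `values` holds the flattened (column-major) surface of
#' individual `ids[j]`; see [GridSpec-class] for the cell order.
#'
#' @slot grid the shared [GridSpec-class]
#' @slot ids,years individual identifiers and their nesting seasons
#' @slot values ncell x n matrix of normalized surface values
#' @export
setClass("SurfaceStack",
  representation(grid = "GridSpec", ids = "character", years = "integer",
                 values = "matrix"))

setValidity("SurfaceStack", function(object) {
  n <- length(object@ids)
  if (ncol(object@values) != n || length(object@years) != n)
    return("ids, years and value columns must agree")
  if (nrow(object@values) != length(object@grid@mask))
    return("value rows must equal the number of grid cells")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  TRUE
})

#' Summed (optionally weighted) importance index raster
#'
#' Cell-wise sum of normalized assignment surfaces, optionally weighted by a
#' per-individual reproductive quantity (eggs or emergents). The values are a
#' probability-weighted index of evidence, not a count of individuals.
#'
#' @slot grid the shared [GridSpec-class]
#' @slot values index raster
#' @slot year a year label or `"overall"`
#' @slot weighting `"count"`, `"eggs"` or `"emergents"`
#' @slot n number of individuals contributing
#' @slot totalWeight sum of the weights (equals `n` for `"count"`)
#' @export
setClass("ImportanceIndex",
  representation(grid = "GridSpec", values = "matrix", year = "character",
                 weighting = "character", n = "integer",
                 totalWeight = "numeric"))

setValidity("ImportanceIndex", function(object) {
  m <- object@grid@mask
  v <- object@values[m]
  if (!all(dim(object@values) == dim(m)))
    return("values must match the grid dimensions")
  if (!object@weighting %in% c("count", "eggs", "emergents"))
    return("weighting must be count, eggs or emergents")
  if (any(v < -1e-12) || any(v > object@totalWeight + 1e-9))
    return("cell values must lie in [0, total weight]")
  TRUE
})

#' Cell-wise emergence-success rate surface
#'
#' Ratio of an emergent-weighted to an egg-weighted importance index: the
#' probability-weighted mean emergence rate of the individuals whose surfaces
#' put mass on the cell. `NA` where the egg index is zero.
#'
#' @slot grid the shared [GridSpec-class]
#' @slot values rate raster in \[0, 1\] where defined
#' @slot year a year label or `"overall"`
#' @slot n number of nests contributing
#' @export
setClass("RateSurface",
  representation(grid = "GridSpec", values = "matrix", year = "character",
                 n = "integer"))

#' Named foraging-hotspot polygons
#'
#' @slot names hotspot names, unique, in fixed display order
#' @slot polygons list of closed two-column (lon, lat) vertex matrices
#' @slot crs coordinate reference system identifier
#' @export
setClass("HotspotSet",
  representation(names = "character", polygons = "list", crs = "character"))

setValidity("HotspotSet", function(object) {
  if (length(object@names) != length(object@polygons))
    return("names and polygons must have equal length")
  if (anyDuplicated(object@names)) return("hotspot names must be unique")
  ok <- vapply(object@polygons, function(p)
    is.matrix(p) && ncol(p) == 2 && nrow(p) >= 4, logical(1))
  if (!all(ok)) return("each polygon needs a two-column vertex matrix (>= 4 rows)")
  TRUE
})

#' Hotspot-by-year contribution table
#'
#' @slot values numeric matrix, hotspots in rows (fixed order), years in columns
#' @slot metric `"female_index"`, `"egg_index"`, `"emergent_index"` or
#'   `"emergence_rate"`
#' @slot normalization `"by_n"`, `"by_hotspot_total"` or `"none"`
#' @slot nPerYear individuals contributing per year column
#' @export
setClass("ContributionTable",
  representation(values = "matrix", metric = "character",
                 normalization = "character", nPerYear = "integer"))

setValidity("ContributionTable", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry hotspot rownames and year colnames")
  if (any(v < -1e-12, na.rm = TRUE))
    return("contribution values must be non-negative")
  if (object@metric == "emergence_rate" && any(v > 1 + 1e-9, na.rm = TRUE))
    return("emergence rates must lie in [0, 1]")
  if (length(object@nPerYear) != ncol(v))
    return("nPerYear must have one entry per year column")
  TRUE
})

#' Tissue-to-epidermis conversion model
#'
#' Linear maps (slope, intercept per element) taking each tissue's isotope
#' values to epidermis equivalents. Epidermis itself must map to the identity.
#' The shipped default coefficients are synthetic placeholders for testing;
#' real analyses must supply the regression coefficients established for their
#' study system via [conversionModel()].
#'
#' @slot table data.frame with columns tissue, slopeC, interceptC, slopeN,
#'   interceptN
#' @export
setClass("ConversionModel", representation(table = "data.frame"))

setValidity("ConversionModel", function(object) {
  tb <- object@table
  need <- c("tissue", "slopeC", "interceptC", "slopeN", "interceptN")
  if (!all(need %in% names(tb)))
    return(paste("conversion table must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(tb$tissue)) return("duplicate tissue in conversion table")
  ep <- tb[tb$tissue == "epidermis", ]
  if (nrow(ep) == 1 &&
      !(ep$slopeC == 1 && ep$interceptC == 0 &&
        ep$slopeN == 1 && ep$interceptN == 0))
    return("epidermis must map to the identity (slope 1, intercept 0)")
  TRUE
})

#' Friedman rank-sum test result
#'
#' @slot statistic tie-corrected chi-square statistic
#' @slot df degrees of freedom (k - 1)
#' @slot p.value asymptotic chi-square p-value
#' @slot p.exact exact within-block permutation p-value (`NA` unless requested)
#' @slot rankSums column rank sums
#' @slot nBlocks number of blocks
#' @export
setClass("FriedmanResult",
  representation(statistic = "numeric", df = "numeric", p.value = "numeric",
                 p.exact = "numeric", rankSums = "numeric",
                 nBlocks = "integer"))

#' All-pairs Conover post-hoc result
#'
#' @slot statistic k x k matrix of pairwise t statistics
#' @slot p.raw,p.adjusted raw and Benjamini-Hochberg-adjusted p-value matrices
#'   (diagonal `NA`)
#' @slot df t-distribution degrees of freedom, (b - 1)(k - 1)
#' @slot letters compact letter display at alpha = 0.05
#' @export
setClass("PosthocResult",
  representation(statistic = "matrix", p.raw = "matrix",
                 p.adjusted = "matrix", df = "numeric", letters = "character"))

#' Synthetic-study scenario
#'
#' Complete, seeded description of a synthetic study: grid geometry, truth
#' isoscape parameters, calibration-area design, hotspot geometry, per-year
#' cohort sizes and hotspot mixture weights, tissue noise, and per-hotspot
#' reproductive-outcome distributions. The seed fully determines every
#' generated dataset.
#'
#' @slot seed integer master seed
#' @slot grid the study [GridSpec-class]
#' @slot fieldC,fieldN truth-field parameter lists: `base`, `gradLat`,
#'   `gradLon` (per-mil per degree), `anomalySD` (per-mil), `anomalyRange`
#'   (degrees)
#' @slot calAreas data.frame of calibration-area boxes with per-area `n`
#' @slot hotspots the seven source [HotspotSet-class] polygons
#' @slot years nesting seasons
#' @slot mixtures year x hotspot mixture-weight matrix (rows sum to 1)
#' @slot cohortSizes,nestCounts per-year sampled females and evaluated nests
#' @slot tissueVar named vector `vC`, `vN`, `r` of among-individual noise
#' @slot clutchMean,clutchSD clutch-size distribution (eggs)
#' @slot emergenceProb per-hotspot emergence probability
#' @slot deadRate,liveRate per-hatchling probabilities of being found dead or
#'   alive in the nest at excavation
#' @slot tissueProps sampling proportions of the three tissue types
#' @slot conversion the [ConversionModel-class] used to emit raw tissue values
#' @export
setClass("Scenario",
  representation(seed = "integer", grid = "GridSpec",
                 fieldC = "list", fieldN = "list",
                 calAreas = "data.frame", hotspots = "HotspotSet",
                 years = "integer", mixtures = "matrix",
                 cohortSizes = "integer", nestCounts = "integer",
                 tissueVar = "numeric", clutchMean = "numeric",
                 clutchSD = "numeric", emergenceProb = "numeric",
                 deadRate = "numeric", liveRate = "numeric",
                 tissueProps = "numeric", conversion = "ConversionModel"))

setValidity("Scenario", function(object) {
  msg <- character()
  if (nrow(object@mixtures) != length(object@years) ||
      ncol(object@mixtures) != length(object@hotspots@names))
    msg <- c(msg, "mixtures must be years x hotspots")
  else if (any(abs(rowSums(object@mixtures) - 1) > 1e-9))
    msg <- c(msg, "mixture rows must sum to 1")
  if (length(object@cohortSizes) != length(object@years) ||
      length(object@nestCounts) != length(object@years))
    msg <- c(msg, "cohortSizes and nestCounts must have one entry per year")
  else if (any(object@nestCounts > object@cohortSizes))
    msg <- c(msg, "nestCounts cannot exceed cohortSizes")
  if (any(object@emergenceProb < 0 | object@emergenceProb > 1))
    msg <- c(msg, "emergence probabilities must lie in [0, 1]")
  tv <- object@tissueVar
  if (!all(c("vC", "vN", "r") %in% names(tv)) ||
      tv["vC"] <= 0 || tv["vN"] <= 0 || abs(tv["r"]) > 1)
    msg <- c(msg, "tissueVar needs positive vC, vN and r in [-1, 1]")
  if (abs(sum(object@tissueProps) - 1) > 1e-9)
    msg <- c(msg, "tissueProps must sum to 1")
  if (length(msg)) msg else TRUE
})
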