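boxPolygon <- function(lonMin, lonMax, latMin, latMax) {
  m <- cbind(lon = c(lonMin, lonMax, lonMax, lonMin, lonMin),
             lat = c(latMin, latMin, latMax, latMax, latMin))
  m
}

#' Default synthetic-study scenario
#'
#' A complete seeded scenario emulating the structure of a nine-season
#' (2007-2015) isotope study of nesting loggerheads: a 0.5-degree Northwest
#' Atlantic shelf grid; smooth dual-isotope truth fields whose gradients are
#' near-orthogonal (d13C predominantly latitudinal, d15N predominantly
#' longitudinal with nearshore enrichment) so the two elements jointly
#' discriminate geography; six calibration areas totalling
#' 227 known-origin individuals, placed to cover the hotspot regions the way
#' tracked animals cover the real foraging range; seven foraging-hotspot
#' source polygons,
#' year-varying hotspot mixture weights with synchronous southern pulses
#' (2007, 2014) and northern pulses (2009, 2012) around a stable east-Florida
#' share of 0.31, per-year cohort sizes summing to 749 females of which 513
#' nests carry fate records, and hotspot-specific clutch-size and emergence
#' distributions spanning a north-low/south-high gradient.
#'
#' @param seed master seed; every generated dataset is a deterministic
#'   function of it
#' @return a [Scenario-class]
#' @export
defaultScenario <- function(seed = 1L) {
  grid <- gridSpec(-85, -60, 23, 45, 0.5)
  hotspots <- new("HotspotSet", names = HOTSPOT_NAMES, crs = "EPSG:4326",
    polygons = list(
      boxPolygon(-76.5, -74,   36,   38.5),   # N_Hatteras
      boxPolygon(-78,   -75.5, 33,   35.5),   # S_Hatteras
      boxPolygon(-81.5, -79.5, 30.5, 33),     # SC_GA
      boxPolygon(-81.5, -79.5, 27,   29.5),   # E_FL
      boxPolygon(-78.5, -76.5, 23,   25),     # Bahamas
      boxPolygon(-83.5, -81,   23,   25),     # FL_Keys
      boxPolygon(-85,   -82.5, 26,   28.5)))  # W_FL
  calAreas <- data.frame(
    area   = CAL_AREAS,
    lonMin = c(-63, -78, -81.5, -79, -83.5, -85),
    lonMax = c(-60.5, -74.5, -79, -75.5, -81, -82.5),
    latMin = c(42.5, 34, 27.5, 23, 23, 25.5),
    latMax = c(44.5, 37.5, 31.5, 25.5, 25.5, 28.5),
    n      = c(12L, 50L, 55L, 40L, 30L, 40L))
  years <- 2007:2015
  south   <- c(0.05, 0.05, 0.08, 0.31, 0.22, 0.19, 0.10)
  north   <- c(0.20, 0.18, 0.10, 0.31, 0.06, 0.05, 0.10)
  neutral <- c(0.10, 0.10, 0.11, 0.31, 0.13, 0.12, 0.13)
  mixtures <- rbind(south, neutral, north, neutral, neutral, north,
                    neutral, south, neutral)
  dimnames(mixtures) <- list(as.character(years), HOTSPOT_NAMES)
  new("Scenario",
      seed = as.integer(seed), grid = grid,
      fieldC = list(base = -6, gradLat = -0.60, gradLon = 0.05,
                    anomalySD = 0.1, anomalyRange = 4),
      fieldN = list(base = 15, gradLat = 0.10, gradLon = -0.50,
                    anomalySD = 0.1, anomalyRange = 4),
      calAreas = calAreas, hotspots = hotspots, years = years,
      mixtures = mixtures,
      cohortSizes = stats::setNames(
        c(63L, 71L, 58L, 70L, 73L, 103L, 98L, 73L, 140L), years),
      nestCounts = stats::setNames(
        c(56L, 47L, 33L, 52L, 50L, 55L, 83L, 73L, 64L), years),
      tissueVar = c(vC = 0.08, vN = 0.08, r = 0.2),
      clutchMean = 113, clutchSD = 20,
      emergenceProb = stats::setNames(
        c(0.55, 0.60, 0.65, 0.70, 0.80, 0.78, 0.72), HOTSPOT_NAMES),
      deadRate = 0.01, liveRate = 0.01,
      tissueProps = c(epidermis = 543, unhatched_egg = 156,
                      red_blood_cells = 50) / 749,
      conversion = defaultConversionModel())
}

# simulate a smooth Gaussian-process anomaly on a coarse sub-grid and
# bilinearly refine to the full grid; exponential covariance on degree
# distances
simulateAnomaly <- function(grid, sd, range, thin = 4L) {
  d <- gridDim(grid)
  if (sd == 0) return(matrix(0, d[1], d[2]))
  la <- latCenters(grid); lo <- lonCenters(grid)
  ia <- unique(c(seq(1L, d[1], by = thin), d[1]))
  io <- unique(c(seq(1L, d[2], by = thin), d[2]))
  pts <- expand.grid(lat = la[ia], lon = lo[io])
  K <- sd^2 * exp(-as.matrix(stats::dist(pts)) / range)
  diag(K) <- diag(K) + 1e-10
  z <- drop(t(chol(K)) %*% stats::rnorm(nrow(pts)))
  coarse <- matrix(z, length(ia), length(io))
  cgrid <- list(lat = la[ia], lon = lo[io])
  # bilinear refinement onto the full grid
  j <- pmin(pmax(findInterval(lo, cgrid$lon), 1L), length(io) - 1L)
  i <- pmin(pmax(findInterval(la, cgrid$lat), 1L), length(ia) - 1L)
  tx <- (lo - cgrid$lon[j]) / (cgrid$lon[j + 1L] - cgrid$lon[j])
  ty <- (la - cgrid$lat[i]) / (cgrid$lat[i + 1L] - cgrid$lat[i])
  out <- matrix(0, d[1], d[2])
  for (cix in seq_len(d[2])) {
    jj <- j[cix]; txx <- tx[cix]
    out[, cix] <- (1 - ty) * ((1 - txx) * coarse[i, jj] +
                              txx * coarse[i, jj + 1L]) +
                  ty * ((1 - txx) * coarse[i + 1L, jj] +
                        txx * coarse[i + 1L, jj + 1L])
  }
  out
}

#' Truth isotope fields of a scenario
#'
#' Each element's true field is `base + gradLat * (lat - latMin) + gradLon *
#' (lon - lonMin)` plus a seeded smooth Gaussian-process anomaly. Fully
#' deterministic given the scenario seed.
#'
#' @param scenario a [Scenario-class]
#' @return list with full-field matrices `C`, `N` and the anomaly components
#'   `anomC`, `anomN`
#' @export
makeTruthFields <- function(scenario) {
  grid <- scenario@grid
  set.seed(scenario@seed + 101L)
  cc <- cellCenters(grid)
  d <- gridDim(grid)
  planar <- function(f)
    matrix(f$base + f$gradLat * (cc[, "lat"] - grid@latMin) +
             f$gradLon * (cc[, "lon"] - grid@lonMin), d[1], d[2])
  anomC <- simulateAnomaly(grid, scenario@fieldC$anomalySD,
                           scenario@fieldC$anomalyRange)
  anomN <- simulateAnomaly(grid, scenario@fieldN$anomalySD,
                           scenario@fieldN$anomalyRange)
  list(C = planar(scenario@fieldC) + anomC,
       N = planar(scenario@fieldN) + anomN,
       anomC = anomC, anomN = anomN)
}

# true field value at arbitrary coordinates: analytic planar part plus
# bilinearly interpolated anomaly
truthAt <- function(scenario, fields, lon, lat, element) {
  f <- if (element == "C") scenario@fieldC else scenario@fieldN
  anom <- if (element == "C") fields$anomC else fields$anomN
  f$base + f$gradLat * (lat - scenario@grid@latMin) +
    f$gradLon * (lon - scenario@grid@lonMin) +
    interpBilinear(scenario@grid, anom, lon, lat)
}

tissueNoise <- function(n, tv) {
  sigma <- matrix(c(tv["vC"], tv["r"] * sqrt(tv["vC"] * tv["vN"]),
                    tv["r"] * sqrt(tv["vC"] * tv["vN"]), tv["vN"]), 2, 2)
  MASS::mvrnorm(n, c(0, 0), sigma)
}

# uniform points inside a polygon by bbox rejection sampling
runifPolygon <- function(n, poly) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    cand <- cbind(stats::runif(m, min(poly[, 1]), max(poly[, 1])),
                  stats::runif(m, min(poly[, 2]), max(poly[, 2])))
    out <- rbind(out, cand[mgcv::in.out(poly, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample synthetic known-origin calibration individuals
#'
#' Draws the configured number of individuals uniformly within each broad
#' calibration-area box, reads the true fields at the drawn locations and adds
#' bivariate among-individual tissue noise. All calibration samples are
#' epidermis.
#'
#' @param scenario a [Scenario-class]
#' @param fields truth fields from [makeTruthFields()]
#' @return calibration data.frame
#' @export
sampleCalibration <- function(scenario, fields) {
  grid <- scenario@grid
  ca <- scenario@calAreas
  if (any(ca$lonMin < grid@lonMin | ca$lonMax > grid@lonMax |
          ca$latMin < grid@latMin | ca$latMax > grid@latMax))
    stop("configuration error: calibration area box outside the grid",
         call. = FALSE)
  set.seed(scenario@seed + 202L)
  rows <- lapply(seq_len(nrow(ca)), function(i) {
    n <- ca$n[i]
    lon <- stats::runif(n, ca$lonMin[i], ca$lonMax[i])
    lat <- stats::runif(n, ca$latMin[i], ca$latMax[i])
    noise <- tissueNoise(n, scenario@tissueVar)
    data.frame(area = ca$area[i], lon = lon, lat = lat,
               d13C = truthAt(scenario, fields, lon, lat, "C") + noise[, 1],
               d15N = truthAt(scenario, fields, lon, lat, "N") + noise[, 2])
  })
  df <- do.call(rbind, rows)
  data.frame(id = sprintf("CAL-%03d", seq_len(nrow(df))),
             year = sample(scenario@years, nrow(df), replace = TRUE),
             tissue = "epidermis", df[c("d13C", "d15N", "lon", "lat", "area")],
             stringsAsFactors = FALSE)
}

#' Sample one year's synthetic nesting cohort
#'
#' Each female draws a latent source hotspot from the year's mixture weights
#' and a uniform location within it; tissue values are the truth at that
#' location plus bivariate noise, emitted in a randomly drawn tissue type (the
#' raw value is the inverse conversion of the epidermis value, so the standard
#' conversion step recovers it exactly). A per-year subset of nests receives
#' fate records: clutch size from a truncated normal, hatched eggs binomial in
#' the hotspot's emergence probability, and small dead/live-at-excavation
#' counts. The latent hotspot is returned separately and must never feed the
#' assignment pipeline.
#'
#' @param scenario a [Scenario-class]
#' @param year one of `scenario@years`
#' @param fields truth fields from [makeTruthFields()]
#' @return list with `samples` (assignment-role data.frame) and `truth`
#'   (id, latent hotspot, true lon/lat)
#' @export
sampleCohort <- function(scenario, year, fields) {
  yi <- match(year, scenario@years)
  if (is.na(yi)) stop("year not in scenario", call. = FALSE)
  set.seed(scenario@seed + 1000L + as.integer(year))
  n <- scenario@cohortSizes[yi]
  k <- length(scenario@hotspots@names)
  hs <- sample.int(k, n, replace = TRUE, prob = scenario@mixtures[yi, ])
  loc <- matrix(NA_real_, n, 2)
  for (h in seq_len(k)) {
    sel <- hs == h
    if (any(sel))
      loc[sel, ] <- runifPolygon(sum(sel), scenario@hotspots@polygons[[h]])
  }
  noise <- tissueNoise(n, scenario@tissueVar)
  epiC <- truthAt(scenario, fields, loc[, 1], loc[, 2], "C") + noise[, 1]
  epiN <- truthAt(scenario, fields, loc[, 1], loc[, 2], "N") + noise[, 2]
  tissue <- sample(names(scenario@tissueProps), n, replace = TRUE,
                   prob = scenario@tissueProps)
  tb <- scenario@conversion@table
  ti <- match(tissue, tb$tissue)
  rawC <- (epiC - tb$interceptC[ti]) / tb$slopeC[ti]
  rawN <- (epiN - tb$interceptN[ti]) / tb$slopeN[ti]
  df <- data.frame(id = sprintf("F%d-%03d", year, seq_len(n)),
                   year = as.integer(year), tissue = tissue,
                   d13C = rawC, d15N = rawN,
                   clutch_size = NA_integer_, hatched = NA_integer_,
                   dead_in_nest = NA_integer_, live_in_nest = NA_integer_,
                   stringsAsFactors = FALSE)
  fate <- sample.int(n, scenario@nestCounts[yi])
  for (i in fate) {
    clutch <- max(1L, as.integer(round(stats::rnorm(1, scenario@clutchMean,
                                                    scenario@clutchSD))))
    hatched <- stats::rbinom(1, clutch, scenario@emergenceProb[hs[i]])
    dead <- stats::rbinom(1, hatched, scenario@deadRate)
    live <- stats::rbinom(1, hatched - dead, scenario@liveRate)
    df$clutch_size[i] <- clutch
    df$hatched[i] <- hatched
    df$dead_in_nest[i] <- dead
    df$live_in_nest[i] <- live
  }
  list(samples = df,
       truth = data.frame(id = df$id,
                          hotspot = scenario@hotspots@names[hs],
                          lon = loc[, 1], lat = loc[, 2],
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Runs [makeTruthFields()], [sampleCalibration()] and [sampleCohort()] for
#' every scenario year, and optionally writes the artifact tree:
#' `calibration.csv`, `cohort_<year>.csv`, `hotspots.geojson`, and a `truth/`
#' sidecar (latent hotspots and true locations) that the analysis pipeline
#' never reads.
#'
#' @param scenario a [Scenario-class]
#' @param outDir optional output directory
#' @return list with `calibration`, `cohort` (all years bound), `truth`,
#'   `hotspots`, `fields`
#' @export
simulateStudy <- function(scenario, outDir = NULL) {
  fields <- makeTruthFields(scenario)
  calibration <- sampleCalibration(scenario, fields)
  per <- lapply(scenario@years, function(y) sampleCohort(scenario, y, fields))
  cohort <- do.call(rbind, lapply(per, `[[`, "samples"))
  truth <- do.call(rbind, lapply(per, `[[`, "truth"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSamples(calibration, file.path(outDir, "calibration.csv"))
    for (i in seq_along(scenario@years))
      writeSamples(per[[i]]$samples,
                   file.path(outDir, sprintf("cohort_%d.csv",
                                             scenario@years[i])))
    writeHotspots(scenario@hotspots, file.path(outDir, "hotspots.geojson"))
    dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
    utils::write.csv(truth, file.path(outDir, "truth", "latent_hotspots.csv"),
                     row.names = FALSE)
  }
  list(calibration = calibration, cohort = cohort, truth = truth,
       hotspots = scenario@hotspots, fields = fields)
}
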