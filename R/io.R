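SAMPLE_COLS <- c("id", "year", "tissue", "d13C", "d15N", "lon", "lat", "area",
                 "clutch_size", "hatched", "dead_in_nest", "live_in_nest")

requiredCols <- function(role) {
  switch(role,
         calibration = c("id", "tissue", "d13C", "d15N", "lon", "lat", "area"),
         assignment  = c("id", "year", "tissue", "d13C", "d15N"),
         stop("role must be 'calibration' or 'assignment'", call. = FALSE))
}

#' Read and validate an isotope sample table
#'
#' Reads a comma-separated sample table (UTF-8, header row, empty cells for
#' missing reproductive fields) and validates it against the schema of the
#' requested role. Calibration tables must carry known foraging coordinates
#' and one of the six broad area labels; assignment tables must carry the
#' nesting year.
#'
#' @param path CSV file
#' @param role `"calibration"` or `"assignment"`
#' @param grid optional [GridSpec-class]; calibration coordinates are then
#'   checked to fall inside it
#' @return a validated data.frame, one row per individual
#' @export
readSamples <- function(path, role = c("calibration", "assignment"),
                        grid = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validateSamples(df, role, grid = grid)
}

#' Validate an in-memory sample table
#'
#' @param df data.frame of samples
#' @inheritParams readSamples
#' @return the data.frame, invisibly validated
#' @export
validateSamples <- function(df, role = c("calibration", "assignment"),
                            grid = NULL) {
  role <- match.arg(role)
  need <- requiredCols(role)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("validation error: duplicated id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- abs(df$d13C) > 100 | abs(df$d15N) > 100
  if (any(bad, na.rm = TRUE))
    stop("validation error: isotope values beyond +/-100 per mil for id(s): ",
         paste(df$id[which(bad)], collapse = ", "), call. = FALSE)
  if (any(is.na(df$d13C)) || any(is.na(df$d15N)))
    stop("validation error: missing isotope values", call. = FALSE)
  if (!all(df$tissue %in% TISSUES))
    stop("validation error: unknown tissue(s): ",
         paste(unique(setdiff(df$tissue, TISSUES)), collapse = ", "),
         call. = FALSE)
  if (role == "calibration") {
    if (!all(df$area %in% CAL_AREAS))
      stop("validation error: unknown area label(s): ",
           paste(unique(setdiff(df$area, CAL_AREAS)), collapse = ", "),
           call. = FALSE)
    if (!is.null(grid)) {
      idx <- cellIndexOf(grid, df$lon, df$lat)
      if (any(is.na(idx[, "row"])))
        stop("validation error: calibration coordinates outside the grid for id(s): ",
             paste(df$id[is.na(idx[, "row"])], collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("clutch_size", "hatched", "dead_in_nest", "live_in_nest"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  repro <- !is.na(df$clutch_size)
  if (any(repro)) {
    r <- df[repro, ]
    if (any(r$clutch_size < 0, na.rm = TRUE))
      stop("validation error: negative clutch_size", call. = FALSE)
    if (any(r$hatched > r$clutch_size, na.rm = TRUE))
      stop("validation error: hatched exceeds clutch_size for id(s): ",
           paste(r$id[which(r$hatched > r$clutch_size)], collapse = ", "),
           call. = FALSE)
    if (any(r$dead_in_nest + r$live_in_nest > r$hatched, na.rm = TRUE))
      stop("validation error: dead + live in nest exceed hatched", call. = FALSE)
  }
  df
}

#' Write a sample table
#'
#' Numeric columns are serialized at full double precision so a write/read
#' round trip reproduces every field exactly. Missing values become empty
#' cells.
#'
#' @param df sample data.frame
#' @param path output CSV path
#' @export
writeSamples <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.double(out[[col]])) {
      s <- sprintf("%.17g", out[[col]])
      s[is.na(out[[col]])] <- NA
      out[[col]] <- s
    }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Build or read a tissue conversion model
#'
#' `conversionModel` builds the model from a coefficient data.frame;
#' `readConversionModel` reads one from a YAML file with one block per tissue
#' (`slopeC`, `interceptC`, `slopeN`, `interceptN`). Epidermis is added as the
#' identity when absent.
#'
#' @param table data.frame with columns tissue, slopeC, interceptC, slopeN,
#'   interceptN
#' @return a [ConversionModel-class]
#' @export
conversionModel <- function(table) {
  if (!"epidermis" %in% table$tissue)
    table <- rbind(table,
                   data.frame(tissue = "epidermis", slopeC = 1, interceptC = 0,
                              slopeN = 1, interceptN = 0))
  new("ConversionModel", table = table)
}

#' @rdname conversionModel
#' @param path YAML file of coefficients
#' @export
readConversionModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  rows <- lapply(names(cfg), function(tis) {
    co <- cfg[[tis]]
    need <- c("slopeC", "interceptC", "slopeN", "interceptN")
    if (!all(need %in% names(co)))
      stop("configuration error: tissue '", tis, "' must define ",
           paste(need, collapse = ", "), call. = FALSE)
    data.frame(tissue = tis, slopeC = co$slopeC, interceptC = co$interceptC,
               slopeN = co$slopeN, interceptN = co$interceptN)
  })
  conversionModel(do.call(rbind, rows))
}

#' Default placeholder conversion model
#'
#' Synthetic slopes/intercepts used by the simulator and examples. They are
#' *not* the regression coefficients established for real loggerhead tissues;
#' analyses of real data must supply those via [conversionModel()].
#'
#' @return a [ConversionModel-class]
#' @export
defaultConversionModel <- function() {
  conversionModel(data.frame(
    tissue = c("epidermis", "unhatched_egg", "red_blood_cells"),
    slopeC = c(1, 0.95, 1.00), interceptC = c(0, 0.50, 1.20),
    slopeN = c(1, 0.98, 1.00), interceptN = c(0, 0.80, 0.60)))
}

#' Read/write hotspot polygons as GeoJSON
#'
#' Hotspots travel as a GeoJSON FeatureCollection with one Polygon feature per
#' hotspot and a `name` property.
#'
#' @param path GeoJSON file
#' @return a [HotspotSet-class]
#' @export
readHotspots <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  nms <- character(); polys <- list()
  for (f in gj$features) {
    if (f$geometry$type != "Polygon")
      stop("hotspot features must be Polygons", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    nms <- c(nms, f$properties$name)
    polys <- c(polys, list(m))
  }
  new("HotspotSet", names = nms, polygons = polys,
      crs = if (!is.null(gj$crs$properties$name)) gj$crs$properties$name
            else "EPSG:4326")
}

#' @rdname readHotspots
#' @param hotspots a [HotspotSet-class]
#' @export
writeHotspots <- function(hotspots, path) {
  feats <- lapply(seq_along(hotspots@names), function(i) {
    ring <- lapply(seq_len(nrow(hotspots@polygons[[i]])), function(k)
      unname(as.numeric(hotspots@polygons[[i]][k, ])))
    list(type = "Feature",
         properties = list(name = hotspots@names[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows from
#' north to south. Masked/`NA` cells are written as the no-data value.
#'
#' @param values raster matrix on `grid` (rows = latitude ascending)
#' @param grid a [GridSpec-class]
#' @param path output file
#' @param nodata no-data sentinel
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  d <- gridDim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
               sprintf("xllcorner %.10g", grid@lonMin),
               sprintf("yllcorner %.10g", grid@latMin),
               sprintf("cellsize %.10g", grid@cellSize),
               sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  for (i in rev(seq_len(d[1])))
    writeLines(paste(sprintf("%.10g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @return `readAsciiGrid` returns `list(values, grid)` with no-data as `NA`
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- utils::read.table(path, skip = 6)
  v <- as.matrix(body)
  dimnames(v) <- NULL
  v[v == h["nodata_value"]] <- NA
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # back to latitude-ascending
  grid <- gridSpec(h["xllcorner"], h["xllcorner"] + h["ncols"] * h["cellsize"],
                   h["yllcorner"], h["yllcorner"] + h["nrows"] * h["cellsize"],
                   h["cellsize"], mask = !is.na(v))
  list(values = v, grid = grid)
}

#' Write a contribution table as CSV
#'
#' Two comment header lines record the metric and the normalization; rows are
#' the hotspots in fixed order, columns the years.
#'
#' @param x a [ContributionTable-class]
#' @param path output CSV
#' @export
writeContributionTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# metric: %s", x@metric),
               sprintf("# normalization: %s", x@normalization)), con)
  df <- data.frame(hotspot = rownames(x@values), x@values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
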