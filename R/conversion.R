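#' Convert tissue isotope values to the common epidermis currency
#'
#' Applies the linear tissue-to-epidermis map of the conversion model to both
#' isotope columns and sets `tissue` to `"epidermis"`. Epidermis rows pass
#' through unchanged (the model maps them by the identity), so the operation
#' is idempotent. All other fields (id, year, reproductive counts) are
#' untouched.
#'
#' @param samples sample data.frame with `tissue`, `d13C`, `d15N`
#' @param model a [ConversionModel-class]
#' @return the data.frame in epidermis currency
#' @examples
#' m <- conversionModel(data.frame(tissue = "unhatched_egg",
#'   slopeC = 1, interceptC = 1.5, slopeN = 1, interceptN = -0.5))
#' s <- data.frame(id = "a", tissue = "unhatched_egg", d13C = -20, d15N = 8)
#' toEpidermis(s, m)[, c("d13C", "d15N")]  # -18.5, 7.5
#' @export
toEpidermis <- function(samples, model) {
  tb <- model@table
  unknown <- setdiff(unique(samples$tissue), tb$tissue)
  if (length(unknown))
    stop("configuration error: no conversion for tissue(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  i <- match(samples$tissue, tb$tissue)
  samples$d13C <- tb$slopeC[i] * samples$d13C + tb$interceptC[i]
  samples$d15N <- tb$slopeN[i] * samples$d15N + tb$interceptN[i]
  samples$tissue <- "epidermis"
  samples
}

#' Emergents per nest
#'
#' Hatchlings that emerged from a nest: hatched eggs minus the dead and live
#' hatchlings still found in the nest at excavation. Vectorized; `NA` inputs
#' propagate.
#'
#' @param hatched,dead_in_nest,live_in_nest non-negative counts
#' @return integer count of emergents, never negative
#' @examples
#' computeEmergents(80, 3, 2)  # 75
#' @export
computeEmergents <- function(hatched, dead_in_nest, live_in_nest) {
  if (any(c(hatched, dead_in_nest, live_in_nest) < 0, na.rm = TRUE))
    stop("validation error: counts must be non-negative", call. = FALSE)
  if (any(dead_in_nest + live_in_nest > hatched, na.rm = TRUE))
    stop("validation error: dead + live in nest exceed hatched", call. = FALSE)
  as.integer(hatched - (dead_in_nest + live_in_nest))
}

#' Emergence success of a nest
#'
#' Emergents divided by clutch size, the standard nest-evaluation metric.
#' Clutch size is the per-nest total recorded at deposition, so disturbed
#' nests with a known initial clutch are still usable.
#'
#' @param emergents,clutch_size non-negative counts; `clutch_size > 0`
#' @return fraction in \[0, 1\]
#' @export
emergenceSuccess <- function(emergents, clutch_size) {
  if (any(clutch_size == 0, na.rm = TRUE))
    stop("undefined rate: clutch_size is zero", call. = FALSE)
  if (any(emergents > clutch_size, na.rm = TRUE))
    stop("validation error: emergents exceed clutch_size", call. = FALSE)
  emergents / clutch_size
}

#' Attach emergents and emergence success to a sample table
#'
#' Convenience wrapper that computes [computeEmergents()] and
#' [emergenceSuccess()] for rows with complete nest-fate records; other rows
#' get `NA`.
#'
#' @param samples sample data.frame
#' @return the data.frame with `emergents` and `emergence_success` columns
#' @export
addNestOutcomes <- function(samples) {
  ok <- !is.na(samples$hatched) & !is.na(samples$dead_in_nest) &
    !is.na(samples$live_in_nest)
  samples$emergents <- NA_integer_
  samples$emergents[ok] <- computeEmergents(
    samples$hatched[ok], samples$dead_in_nest[ok], samples$live_in_nest[ok])
  samples$emergence_success <- NA_real_
  rate <- ok & !is.na(samples$clutch_size) & samples$clutch_size > 0
  samples$emergence_success[rate] <-
    emergenceSuccess(samples$emergents[rate], samples$clutch_size[rate])
  samples
}
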