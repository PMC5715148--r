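# build a stack of simple synthetic surfaces directly (no kriging needed)
makeStack <- function(n = 6, g = tinyGrid(5, 5), years = NULL, seed = 31) {
  set.seed(seed)
  ncell <- length(g@mask)
  vals <- sapply(seq_len(n), function(i) {
    v <- runif(ncell)
    v / max(v)
  })
  if (is.null(years)) years <- rep(2007L, n)
  new("SurfaceStack", grid = g, ids = sprintf("T%02d", seq_len(n)),
      years = as.integer(years), values = vals)
}

test_that("the foraging index is the cell-wise sum of surfaces", {
  st <- makeStack(6, years = c(2007, 2007, 2007, 2008, 2008, 2008))
  one <- new("SurfaceStack", grid = st@grid, ids = st@ids[1],
             years = st@years[1], values = st@values[, 1, drop = FALSE])
  expect_equal(foragingIndex(one)@values,
               matrix(st@values[, 1], 5))

  # linearity: two identical surfaces double the index; the union of two
  # cohorts is the sum of their indices
  two <- new("SurfaceStack", grid = st@grid, ids = c("a", "b"),
             years = c(2007L, 2007L), values = st@values[, c(1, 1)])
  expect_equal(foragingIndex(two)@values, 2 * foragingIndex(one)@values)
  expect_equal(foragingIndex(st)@values,
               foragingIndex(st, 2007)@values + foragingIndex(st, 2008)@values)

  # brute-force accumulation oracle on 20 surfaces
  st20 <- makeStack(20)
  acc <- matrix(0, 5, 5)
  for (j in 1:20) acc <- acc + matrix(st20@values[, j], 5)
  expect_equal(foragingIndex(st20)@values, acc)
  expect_equal(foragingIndex(st20)@n, 20L)

  expect_error(foragingIndex(st, 1999), "empty cohort")
})

test_that("weighted indices scale and factorize as products", {
  st <- makeStack(5)
  w1 <- stats::setNames(c(100, rep(NA, 4)), st@ids)
  one <- suppressWarnings(weightedIndex(st, w1, weighting = "eggs"))
  expect_equal(one@values, 100 * matrix(st@values[, 1], 5))
  expect_equal(one@n, 1L)

  # equal weights factor out
  wAll <- stats::setNames(rep(7, 5), st@ids)
  expect_equal(weightedIndex(st, wAll, weighting = "eggs")@values,
               7 * foragingIndex(st)@values)

  # unit weights reproduce the unweighted index bit-for-bit
  wUnit <- stats::setNames(rep(1, 5), st@ids)
  expect_identical(weightedIndex(st, wUnit, weighting = "eggs")@values,
                   foragingIndex(st)@values)

  # mixed weights equal a brute-force loop
  set.seed(7)
  w <- stats::setNames(rpois(5, 110), st@ids)
  acc <- matrix(0, 5, 5)
  for (j in 1:5) acc <- acc + w[j] * matrix(st@values[, j], 5)
  expect_equal(weightedIndex(st, w, weighting = "emergents")@values, acc,
               ignore_attr = TRUE)

  expect_warning(weightedIndex(st, w1, weighting = "eggs"), "excluded")
})

test_that("the emergence-rate surface is the weighted mean nest rate per cell", {
  st <- makeStack(2)
  eggs <- stats::setNames(c(100, 120), st@ids)
  emergents <- stats::setNames(c(75, 102), st@ids)
  eggIdx <- weightedIndex(st, eggs, weighting = "eggs")
  emeIdx <- weightedIndex(st, emergents, weighting = "emergents")
  rate <- emergenceRateSurface(eggIdx, emeIdx)

  # hand-computed probability-weighted mean at three cells
  for (cell in c(1, 9, 23)) {
    s <- st@values[cell, ]
    expect_equal(as.numeric(rate@values)[cell],
                 sum(emergents * s) / sum(eggs * s))
  }
  # bounded by the per-nest rates (weighted-mean property)
  r <- emergents / eggs
  expect_true(all(rate@values >= min(r) - 1e-12 &
                  rate@values <= max(r) + 1e-12, na.rm = TRUE))

  # identical egg/emergent counts give a ratio of exactly 1
  same <- emergenceRateSurface(eggIdx, eggIdx)
  expect_true(all(same@values[!is.na(same@values)] == 1))

  # single nest: the surface is the scalar rate wherever defined
  one <- new("SurfaceStack", grid = st@grid, ids = st@ids[1],
             years = st@years[1], values = st@values[, 1, drop = FALSE])
  r1 <- emergenceRateSurface(
    weightedIndex(one, eggs, weighting = "eggs"),
    weightedIndex(one, emergents, weighting = "emergents"))
  expect_true(all(abs(r1@values - 0.75) < 1e-12, na.rm = TRUE))
})

test_that("hotspot tables sum index mass by cell-center membership", {
  g <- tinyGrid(6, 6)
  hs <- new("HotspotSet", names = c("A", "B"), crs = "EPSG:4326",
            polygons = list(
              cbind(lon = c(-80, -78, -78, -80, -80),
                    lat = c(25, 25, 27, 27, 25)),
              cbind(lon = c(-77, -75, -75, -77, -77),
                    lat = c(28, 28, 30, 30, 28))))
  mem <- hotspotCellMembership(hs, g)
  expect_equal(sum(mem$A), 4L)  # 2x2 cells of 1 degree

  # a surface fully concentrated in A: all of A's mass, none in B
  ncell <- length(g@mask)
  v <- rep(0, ncell); v[mem$A] <- 1
  st <- new("SurfaceStack", grid = g, ids = "t", years = 2007L,
            values = matrix(v, ncol = 1))
  idx <- list("2007" = foragingIndex(st))
  tb <- hotspotTable(idx, hs, normalize = "by_n")
  expect_equal(tb@values["A", "2007"], sum(v))
  expect_equal(tb@values["B", "2007"], 0)

  # by_hotspot_total columns sum to one
  st2 <- makeStack(4, g = g)
  tb2 <- hotspotTable(list("2007" = foragingIndex(st2)), hs,
                      normalize = "by_hotspot_total")
  expect_equal(colSums(tb2@values), c("2007" = 1))

  # a polygon covering no cell center is an error
  hsBad <- new("HotspotSet", names = "empty", crs = "EPSG:4326",
               polygons = list(cbind(lon = c(-79.9, -79.8, -79.8, -79.9, -79.9),
                                     lat = c(25.9, 25.9, 25.95, 25.95, 25.9))))
  expect_error(hotspotTable(idx, hsBad), "empty hotspot")

  # emergence-rate tables are zonal-ratio rates in [0, 1]
  eggs <- stats::setNames(rep(100, 4), st2@ids)
  emergents <- stats::setNames(c(60, 70, 80, 90), st2@ids)
  rt <- emergenceRateTable(
    list("2007" = weightedIndex(st2, eggs, weighting = "eggs")),
    list("2007" = weightedIndex(st2, emergents, weighting = "emergents")), hs)
  expect_true(all(rt@values >= 0.6 & rt@values <= 0.9))
})
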