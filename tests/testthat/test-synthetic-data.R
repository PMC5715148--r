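test_that("the generator is fully deterministic under its seed", {
  scn <- smallScenario(5L)
  a <- simulateStudy(scn)
  b <- simulateStudy(scn)
  expect_identical(a$calibration, b$calibration)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)

  other <- simulateStudy(smallScenario(6L))
  expect_false(identical(a$cohort$d13C, other$cohort$d13C))

  # byte-identical CSV output across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateStudy(scn, d1); simulateStudy(scn, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("truth fields follow the configured planar structure", {
  scn <- smallScenario(2L)
  # gradient and anomaly off: constant raster at the base value
  s0 <- scn
  s0@fieldC <- list(base = -12, gradLat = 0, gradLon = 0, anomalySD = 0,
                    anomalyRange = 4)
  f0 <- makeTruthFields(s0)
  expect_true(all(f0$C == -12))

  # pure gradient: differences equal gradient times coordinate offsets
  s1 <- s0
  s1@fieldC <- list(base = -12, gradLat = 0.5, gradLon = 0, anomalySD = 0,
                    anomalyRange = 4)
  f1 <- makeTruthFields(s1)
  lats <- latCenters(scn@grid)
  expect_equal(f1$C[10, 3] - f1$C[2, 3], 0.5 * (lats[10] - lats[2]))

  # anomaly on: seeded determinism, different seeds differ
  sA <- scn; sB <- scn; sB@seed <- 99L
  expect_identical(makeTruthFields(sA)$C, makeTruthFields(sA)$C)
  expect_false(identical(makeTruthFields(sA)$anomC,
                         makeTruthFields(sB)$anomC))
})

test_that("calibration sampling reproduces locations, noise and bookkeeping", {
  scn <- smallScenario(3L)
  fields <- makeTruthFields(scn)

  # zero noise: tissue values equal the truth at the drawn location
  s0 <- scn
  s0@tissueVar <- c(vC = 1e-12, vN = 1e-12, r = 0)
  cal0 <- sampleCalibration(s0, fields)
  expect_equal(cal0$d13C,
               isoforage:::truthAt(s0, fields, cal0$lon, cal0$lat, "C"),
               tolerance = 1e-4)

  # per-area counts as configured; locations inside their boxes
  cal <- sampleCalibration(scn, fields)
  expect_equal(as.integer(table(cal$area)[scn@calAreas$area]),
               scn@calAreas$n)
  for (i in seq_len(nrow(scn@calAreas))) {
    a <- scn@calAreas[i, ]
    sel <- cal$area == a$area
    expect_true(all(cal$lon[sel] >= a$lonMin & cal$lon[sel] <= a$lonMax))
    expect_true(all(cal$lat[sel] >= a$latMin & cal$lat[sel] <= a$latMax))
  }

  # law of large numbers: sample moments near the configured noise
  big <- scn
  big@calAreas <- data.frame(area = "SAB", lonMin = -80, lonMax = -79.9,
                             latMin = 30, latMax = 30.1, n = 2000L)
  calBig <- sampleCalibration(big, fields)
  expect_lt(abs(var(calBig$d13C) - 0.08) / 0.08, 0.10)
  expect_lt(abs(var(calBig$d15N) - 0.08) / 0.08, 0.10)
  expect_lt(abs(cor(calBig$d13C, calBig$d15N) - 0.2), 0.2 * 0.5)
})

test_that("cohort sampling honours mixtures and reproductive distributions", {
  scn <- smallScenario(4L)
  fields <- makeTruthFields(scn)

  # degenerate mixture: every latent label is the chosen hotspot
  s1 <- scn
  s1@mixtures[1, ] <- c(0, 0, 0, 1, 0, 0, 0)
  c1 <- sampleCohort(s1, 2007L, fields)
  expect_true(all(c1$truth$hotspot == "E_FL"))

  # emergence probability 1 with no dead/live: emergents equal the clutch
  s2 <- scn
  s2@emergenceProb[] <- 1
  s2@deadRate <- 0; s2@liveRate <- 0
  c2 <- addNestOutcomes(sampleCohort(s2, 2008L, fields)$samples)
  fate <- !is.na(c2$clutch_size)
  expect_equal(sum(fate), unname(scn@nestCounts["2008"]))
  expect_equal(c2$emergents[fate], c2$clutch_size[fate])
  expect_true(all(c2$emergence_success[fate] == 1))

  # multinomial frequencies approach the weights at large n
  s3 <- scn
  s3@cohortSizes["2009"] <- 10000L
  s3@nestCounts["2009"] <- 0L
  s3@mixtures[3, ] <- c(0.5, 0.3, 0.2, 0, 0, 0, 0)
  c3 <- sampleCohort(s3, 2009L, fields)
  freq <- table(factor(c3$truth$hotspot,
                       levels = scn@hotspots@names)) / 10000
  expect_true(all(abs(as.numeric(freq) - s3@mixtures[3, ]) < 0.02))

  # locations fall inside the latent hotspot polygon
  for (h in unique(c1$truth$hotspot)) {
    poly <- scn@hotspots@polygons[[match(h, scn@hotspots@names)]]
    sel <- c1$truth$hotspot == h
    expect_true(all(mgcv::in.out(poly,
                                 cbind(c1$truth$lon[sel], c1$truth$lat[sel]))))
  }
})

test_that("raw tissue values invert exactly through the conversion step", {
  scn <- smallScenario(8L)
  sim <- simulateStudy(scn)
  conv <- toEpidermis(sim$cohort, scn@conversion)
  # converting a second time changes nothing
  expect_equal(toEpidermis(conv, scn@conversion), conv)
  # epidermis rows were already in the common currency
  epi <- sim$cohort$tissue == "epidermis"
  expect_identical(conv$d13C[epi], sim$cohort$d13C[epi])
  # non-epidermis rows moved
  expect_false(any(conv$d13C[!epi] == sim$cohort$d13C[!epi]))
})
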