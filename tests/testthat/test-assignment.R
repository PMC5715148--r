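test_that("pooled tissue covariance averages per-area moments", {
  # identical groups reproduce the group moments exactly
  set.seed(21)
  g1 <- MASS::mvrnorm(30, c(-14, 9),
                      matrix(c(0.5, 0.2 * sqrt(0.2), 0.2 * sqrt(0.2), 0.4),
                             2, 2))
  areas <- c("CAN", "MAB", "SAB", "SNWA", "FLKeys", "SWFL")
  cal <- do.call(rbind, lapply(areas,
    function(a) data.frame(area = a, d13C = g1[, 1], d15N = g1[, 2])))
  tc <- pooledTissueCovariance(cal)
  expect_equal(tc@vC, var(g1[, 1]))
  expect_equal(tc@vN, var(g1[, 2]))
  expect_equal(tc@r, cor(g1[, 1], g1[, 2]))

  # two-area toy equals the hand-computed mean of per-group moments
  a <- data.frame(area = "A", d13C = c(-15, -14, -13, -12),
                  d15N = c(8, 9, 7, 10))
  b <- data.frame(area = "B", d13C = c(-10, -9.5, -11, -10.5),
                  d15N = c(12, 12.5, 11, 13))
  tc2 <- pooledTissueCovariance(rbind(a, b))
  vC <- mean(c(var(a$d13C), var(b$d13C)))
  vN <- mean(c(var(a$d15N), var(b$d15N)))
  r <- mean(c(cor(a$d13C, a$d15N), cor(b$d13C, b$d15N)))
  expect_equal(tc2@vC, vC)
  expect_equal(tc2@vN, vN)
  expect_equal(tc2@r, r)
  expect_equal(tc2@cov, r * sqrt(vC * vN))
  # |r| <= 1 forces the implied matrix PSD
  expect_gte(tc2@vC * tc2@vN - tc2@cov^2, 0)

  expect_error(pooledTissueCovariance(rbind(a, b[1:2, ])),
               "insufficient group.*B")
})

test_that("the covariance field adds squared kriging errors to the diagonal", {
  g <- tinyGrid(4, 4)
  tc <- toyTissueCov(0.5, 0.4, r = 0.1 / sqrt(0.5 * 0.4))  # cov exactly 0.1
  # zero kriging error: the field is the tissue matrix everywhere
  cf0 <- buildCovField(tc, toyIsoscape(g, -14, 0, "C"),
                       toyIsoscape(g, 9, 0, "N"))
  expect_true(all(cf0@varC == 0.5) && all(cf0@varN == 0.4))
  expect_equal(cf0@covCN, 0.1)

  # one cell with (seC, seN) = (0.3, 0.2): sigma = [[.59,.1],[.1,.44]]
  seC <- matrix(0, 4, 4); seC[2, 3] <- 0.3
  seN <- matrix(0, 4, 4); seN[2, 3] <- 0.2
  cf <- buildCovField(tc, toyIsoscape(g, -14, seC, "C"),
                      toyIsoscape(g, 9, seN, "N"))
  expect_equal(cf@varC[2, 3], 0.59)
  expect_equal(cf@varN[2, 3], 0.44)

  # randomized standard errors never break positive definiteness
  set.seed(9)
  cfr <- buildCovField(tc,
                       toyIsoscape(g, -14, matrix(runif(16, 0, 2), 4), "C"),
                       toyIsoscape(g, 9, matrix(runif(16, 0, 2), 4), "N"))
  expect_true(all(cfr@varC * cfr@varN - cfr@covCN^2 > 0))
})

test_that("the bivariate normal density matches its closed form", {
  expect_equal(bivariateDensity(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi))
  # symmetry about the mean
  sig <- matrix(c(1.2, 0.4, 0.4, 0.8), 2, 2)
  mu <- c(-14, 9); d <- c(0.7, -0.3)
  expect_equal(bivariateDensity(mu + d, mu, sig),
               bivariateDensity(mu - d, mu, sig))
  # hand-evaluated quadratic form at x = (1, 0), sigma = [[2,.5],[.5,1]]
  sig2 <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  q <- drop(t(c(1, 0)) %*% solve(sig2) %*% c(1, 0))
  expect_equal(bivariateDensity(c(1, 0), c(0, 0), sig2),
               exp(-q / 2) / (2 * pi * sqrt(det(sig2))))
  expect_error(bivariateDensity(c(0, 0), c(0, 0),
                                matrix(c(1, 1, 1, 1), 2, 2)),
               "positive definite")
})

test_that("assignment surfaces are max-normalized posterior rasters", {
  # 3-cell toy: means (-18,6), (-14,10), (-10,14), shared identity covariance,
  # sample at the middle cell -> values (exp(-16), 1, exp(-16))
  g <- tinyGrid(1, 3)
  isoC <- toyIsoscape(g, matrix(c(-18, -14, -10), 1), 0, "C")
  isoN <- toyIsoscape(g, matrix(c(6, 10, 14), 1), 0, "N")
  cf <- buildCovField(new("TissueCov", vC = 1, vN = 1, r = 0, cov = 0,
                          perArea = list()), isoC, isoN)
  s <- data.frame(id = "t1", year = 2007L, tissue = "epidermis",
                  d13C = -14, d15N = 10)
  surf <- assignmentSurface(s, isoC, isoN, cf)
  expect_equal(as.numeric(surf@values), c(exp(-16), 1, exp(-16)))
  expect_equal(max(surf@values), 1)
  expect_gte(min(surf@values), 0)

  # underflow safety: a distant sample with tiny covariance still normalizes
  cfTight <- buildCovField(new("TissueCov", vC = 1e-3, vN = 1e-3, r = 0,
                               cov = 0, perArea = list()), isoC, isoN)
  far <- data.frame(id = "t2", year = 2007L, tissue = "epidermis",
                    d13C = -60, d15N = 60)
  sf <- assignmentSurface(far, isoC, isoN, cfTight)
  expect_equal(max(sf@values, na.rm = TRUE), 1)

  expect_error(assignmentSurface(
    data.frame(id = "x", year = 2007L, tissue = "unhatched_egg",
               d13C = -14, d15N = 10), isoC, isoN, cf), "epidermis")
})

test_that("surfaces equal independent brute-force evaluation to 1e-10", {
  set.seed(14)
  g <- tinyGrid(10, 10, cell = 0.5)
  isoC <- toyIsoscape(g, matrix(-20 + 10 * runif(100), 10),
                      matrix(runif(100, 0, 0.5), 10), "C")
  isoN <- toyIsoscape(g, matrix(5 + 8 * runif(100), 10),
                      matrix(runif(100, 0, 0.5), 10), "N")
  cf <- buildCovField(toyTissueCov(), isoC, isoN)
  for (k in 1:3) {
    x <- c(runif(1, -20, -10), runif(1, 5, 13))
    surf <- assignmentSurface(
      data.frame(id = "t", year = 2007L, tissue = "epidermis",
                 d13C = x[1], d15N = x[2]), isoC, isoN, cf)
    oracle <- bruteForceSurface(x[1], x[2], isoC, isoN, cf)
    expect_equal(surf@values, oracle, tolerance = 1e-10)
    # normalization is invariant to any positive rescaling of the densities
    expect_equal(surf@values, bruteForceSurface(x[1], x[2], isoC, isoN, cf,
                                                scale = 1e280),
                 tolerance = 1e-10)
  }
})

test_that("with constant covariance the surface decreases in Mahalanobis distance", {
  set.seed(15)
  g <- tinyGrid(8, 8)
  isoC <- toyIsoscape(g, matrix(seq(-20, -8, length.out = 64), 8), 0, "C")
  isoN <- toyIsoscape(g, matrix(rep(seq(6, 14, length.out = 8), each = 8), 8),
                      0, "N")
  tc <- toyTissueCov(0.6, 0.5, 0.3)
  cf <- buildCovField(tc, isoC, isoN)
  x <- c(-13.7, 9.4)
  surf <- assignmentSurface(
    data.frame(id = "t", year = 2007L, tissue = "epidermis",
               d13C = x[1], d15N = x[2]), isoC, isoN, cf)
  sigInv <- solve(matrix(c(tc@vC, tc@cov, tc@cov, tc@vN), 2, 2))
  maha <- mapply(function(mC, mN) {
    d <- c(x[1] - mC, x[2] - mN)
    drop(t(d) %*% sigInv %*% d)
  }, isoC@mean, isoN@mean)
  ord <- order(maha)
  expect_true(all(diff(as.numeric(surf@values)[ord]) <= 1e-12))
})

test_that("calibration validation reads the surface at the true (snapped) cell", {
  g <- tinyGrid(6, 6)
  isoC <- toyIsoscape(g, matrix(seq(-20, -10, length.out = 36), 6), 0, "C")
  isoN <- toyIsoscape(g, matrix(seq(14, 6, length.out = 36), 6), 0, "N")
  cf <- buildCovField(toyTissueCov(), isoC, isoN)
  cc <- cellCenters(g)
  k <- 15
  cal <- data.frame(id = "known", year = 2007L, tissue = "epidermis",
                    d13C = isoC@mean[k], d15N = isoN@mean[k],
                    lon = cc[k, "lon"], lat = cc[k, "lat"], area = "SAB")
  st <- assignSamples(cal, isoC, isoN, cf)
  v <- validateCalibration(st, cal)
  # the animal sits exactly at its surface's argmax
  expect_equal(unname(v$values["known"]), 1)
  expect_equal(v$median, 1)

  # true location on a masked-out cell snaps to the nearest ocean neighbour
  m <- matrix(TRUE, 6, 6)
  idx <- cellIndexOf(g, cc[k, "lon"], cc[k, "lat"])
  m[idx[1, "row"], idx[1, "col"]] <- FALSE
  g2 <- tinyGrid(6, 6, mask = m)
  isoC2 <- toyIsoscape(g2, matrix(seq(-20, -10, length.out = 36), 6), 0, "C")
  isoN2 <- toyIsoscape(g2, matrix(seq(14, 6, length.out = 36), 6), 0, "N")
  cf2 <- buildCovField(toyTissueCov(), isoC2, isoN2)
  st2 <- assignSamples(cal, isoC2, isoN2, cf2)
  v2 <- validateCalibration(st2, cal)
  expect_true(is.finite(v2$values["known"]) && v2$values["known"] > 0)
})
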