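# shared fixtures built in code; no data files

# tiny all-ocean grid with 1-degree cells
tinyGrid <- function(nlat = 5, nlon = 5, cell = 1, lon0 = -80, lat0 = 25,
                     mask = NULL) {
  gridSpec(lon0, lon0 + nlon * cell, lat0, lat0 + nlat * cell, cell,
           mask = mask)
}

# isoscape with prescribed mean/se matrices (no kriging involved)
toyIsoscape <- function(grid, mean, se = 0, element = "C") {
  d <- gridDim(grid)
  if (length(mean) == 1) mean <- matrix(mean, d[1], d[2])
  if (length(se) == 1) se <- matrix(se, d[1], d[2])
  mean[!grid@mask] <- NA; se[!grid@mask] <- NA
  new("Isoscape", element = element, mean = mean, se = se, grid = grid,
      variogram = list(family = "exponential", nugget = 0, psill = 1,
                       range = 100))
}

toyTissueCov <- function(vC = 0.5, vN = 0.4, r = 0.2) {
  new("TissueCov", vC = vC, vN = vN, r = r, cov = r * sqrt(vC * vN),
      perArea = list())
}

# a quick-to-run scenario: 1-degree cells, three seasons, small cohorts
smallScenario <- function(seed = 1L) {
  scn <- defaultScenario(seed)
  scn@grid <- gridSpec(-85, -60, 23, 45, 1)
  scn@years <- 2007:2009
  scn@mixtures <- scn@mixtures[1:3, , drop = FALSE]
  scn@cohortSizes <- stats::setNames(c(30L, 35L, 40L), scn@years)
  scn@nestCounts <- stats::setNames(c(25L, 30L, 35L), scn@years)
  scn
}

# independent brute-force bivariate-normal surface (the oracle for the
# assignment step): direct per-cell evaluation with solve(), then rescale
bruteForceSurface <- function(xC, xN, isoC, isoN, covField, scale = 1) {
  d <- gridDim(covField@grid)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!covField@grid@mask[i, j]) next
    sigma <- matrix(c(covField@varC[i, j], covField@covCN,
                      covField@covCN, covField@varN[i, j]), 2, 2)
    diff <- c(xC - isoC@mean[i, j], xN - isoN@mean[i, j])
    out[i, j] <- scale *
      exp(-0.5 * drop(t(diff) %*% solve(sigma) %*% diff)) /
      (2 * pi * sqrt(det(sigma)))
  }
  out / max(out, na.rm = TRUE)
}

# independent rank-test oracles, coded from the textbook formulas
oracleFriedmanStat <- function(x) {
  b <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  Rj <- colSums(r)
  num <- 12 * sum((Rj - b * (k + 1) / 2)^2)
  ties <- sum(unlist(lapply(seq_len(b), function(i) {
    t <- table(r[i, ]); sum(t^3 - t)
  })))
  den <- b * k * (k + 1) - ties / (k - 1)
  if (den <= 0) 0 else num / den
}

oracleConover <- function(x) {
  b <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  Rj <- colSums(r)
  A1 <- sum(r^2)
  df <- (b - 1) * (k - 1)
  se <- sqrt(2 * (b * A1 - sum(Rj^2)) / df)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tt <- if (se <= 1e-12) { if (Rj[i] == Rj[j]) 0 else Inf }
          else (Rj[i] - Rj[j]) / se
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df)
  }
  p
}

# all permutations of 1:k, coded independently of the package
oraclePerms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in oraclePerms(k - 1L))
    for (pos in 0:(k - 1L))
      out <- c(out, list(append(p, k, after = pos)))
  out
}

# exact within-block permutation p-value of the Friedman statistic
oracleExactFriedmanP <- function(x) {
  b <- nrow(x); k <- ncol(x)
  perms <- oraclePerms(k)
  obs <- oracleFriedmanStat(x)
  grid <- do.call(expand.grid, rep(list(seq_along(perms)), b))
  stats <- apply(grid, 1, function(ix) {
    xp <- x
    for (i in seq_len(b)) xp[i, ] <- x[i, perms[[ix[i]]]]
    oracleFriedmanStat(xp)
  })
  mean(stats >= obs - 1e-12)
}
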