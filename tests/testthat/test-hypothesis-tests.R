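test_that("the Friedman statistic matches the classical tie-corrected form", {
  # identical columns: every block fully tied, no signal
  flat <- matrix(5, nrow = 4, ncol = 3)
  r0 <- friedmanRankTest(flat)
  expect_equal(r0@statistic, 0)
  expect_equal(r0@p.value, 1)

  # random tables, with and without ties, against stats::friedman.test and
  # an independently coded textbook formula
  set.seed(61)
  for (i in 1:6) {
    x <- if (i > 3) matrix(sample(1:5, 36, replace = TRUE), 9, 4)  # ties
         else matrix(rnorm(36), 9, 4)
    if (any(apply(x, 2, var) == 0)) next
    ours <- friedmanRankTest(x)
    ref <- stats::friedman.test(x)
    expect_equal(ours@statistic, unname(ref$statistic))
    expect_equal(ours@p.value, unname(ref$p.value))
    expect_equal(ours@statistic, oracleFriedmanStat(x))
    expect_equal(ours@df, 3)
  }

  # invariance under strictly monotone within-block transforms
  x <- matrix(rnorm(28), 4, 7)
  expect_equal(friedmanRankTest(exp(x))@statistic,
               friedmanRankTest(x)@statistic)
  # with k = 2 the statistic reduces to the sign-test form (R1 - R2)^2 / b
  y <- matrix(rnorm(20), 10, 2)
  r <- t(apply(y, 1, rank))
  expect_equal(friedmanRankTest(y)@statistic,
               (sum(r[, 1]) - sum(r[, 2]))^2 / 10)

  expect_error(friedmanRankTest(matrix(c(1, NA, 2, 3), 2, 2)), "missing cell")
})

test_that("exact permutation p-values agree with exhaustive enumeration", {
  set.seed(62)
  for (dims in list(c(3, 3), c(4, 3), c(4, 2))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    ours <- friedmanRankTest(x, exact = TRUE)
    expect_equal(ours@statistic, oracleFriedmanStat(x))
    expect_equal(ours@p.exact, oracleExactFriedmanP(x))
    expect_gt(ours@p.exact, 0)
    expect_lte(ours@p.exact, 1)
  }
})

test_that("Conover all-pairs tests match the textbook formula and BH rules", {
  flat <- matrix(2, 5, 3)
  p0 <- conoverPosthoc(flat)
  ut <- upper.tri(p0@p.raw)
  expect_true(all(p0@p.raw[ut] == 1))
  expect_true(all(p0@p.adjusted[ut] == 1))

  set.seed(63)
  for (i in 1:4) {
    x <- matrix(rnorm(12), 4, 3)
    ours <- conoverPosthoc(x)
    oracle <- oracleConover(x)
    expect_equal(ours@p.raw, oracle, ignore_attr = TRUE)
    expect_equal(ours@df, 6)
    # BH never lowers a p-value and preserves the raw ordering
    iu <- upper.tri(ours@p.raw)
    expect_true(all(ours@p.adjusted[iu] >= ours@p.raw[iu] - 1e-12))
    # adjusted p-values are monotone non-decreasing in raw-p order
    expect_true(all(diff(ours@p.adjusted[iu][order(ours@p.raw[iu])])
                    >= -1e-12))
    expect_true(all(ours@p.adjusted[iu] <= 1))
  }

  # Benjamini-Hochberg step-up arithmetic: (.01,.02,.03,.5) adjusts to
  # (.04,.04,.04,.5) since 0.01*4/1 = 0.02*4/2 = 0.04 > 0.03*4/3 is capped
  # by the cumulative minimum from the largest p
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("compact letter displays separate exactly the significant pairs", {
  labs <- c("A", "B", "C")
  pAll <- matrix(1, 3, 3, dimnames = list(labs, labs))
  expect_equal(unname(letterDisplay(pAll)), c("a", "a", "a"))

  pNone <- matrix(0.001, 3, 3, dimnames = list(labs, labs))
  diag(pNone) <- NA
  expect_equal(unname(letterDisplay(pNone)), c("a", "b", "c"))

  # only the pair (1, 3) significant -> a, ab, b
  p13 <- matrix(1, 3, 3, dimnames = list(labs, labs))
  p13[1, 3] <- p13[3, 1] <- 0.01
  expect_equal(unname(letterDisplay(p13)), c("a", "ab", "b"))

  # sharing a letter is equivalent to non-significance, on random patterns
  set.seed(64)
  for (i in 1:5) {
    k <- 5
    p <- matrix(1, k, k)
    sig <- matrix(runif(k * k) < 0.3, k, k)
    sig[lower.tri(sig, diag = TRUE)] <- FALSE
    p[sig | t(sig)] <- 0.01
    lt <- letterDisplay(p)
    share <- function(a, b)
      length(intersect(strsplit(lt[a], "")[[1]], strsplit(lt[b], "")[[1]])) > 0
    for (a in 1:(k - 1)) for (b in (a + 1):k)
      expect_equal(share(a, b), p[a, b] >= 0.05)
  }
})

test_that("contribution tables feed the rank tests with years as blocks", {
  set.seed(65)
  vals <- matrix(abs(rnorm(7 * 9, 10, 3)), 7, 9,
                 dimnames = list(paste0("H", 1:7), 2007:2015))
  tb <- new("ContributionTable", values = vals, metric = "female_index",
            normalization = "by_n", nPerYear = rep(50L, 9))
  ft <- friedmanRankTest(tb)
  expect_equal(ft@statistic, friedmanRankTest(t(vals))@statistic)
  expect_equal(ft@df, 6)
  ph <- conoverPosthoc(tb)
  expect_equal(dim(ph@p.adjusted), c(7, 7))
  expect_equal(length(ph@letters), 7)
})
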