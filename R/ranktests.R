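# within-block (row-wise) average ranks
blockRanks <- function(x) t(apply(x, 1L, rank))

checkRankTable <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2 || ncol(x) < 2)
    stop("need a complete blocks x treatments matrix (b >= 2, k >= 2)",
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("missing cell in the block design; no imputation is done",
         call. = FALSE)
  x
}

# tie-corrected Friedman statistic in Conover's form:
#   (k-1) * (sum R_j^2 - b^2 k (k+1)^2 / 4) / (A1 - b k (k+1)^2 / 4)
# algebraically equal to the classical 12 sum (R_j - b(k+1)/2)^2 /
# (b k (k+1) - sum(t^3 - t)/(k-1)) form
friedmanStat <- function(r) {
  b <- nrow(r); k <- ncol(r)
  Rj <- colSums(r)
  A1 <- sum(r^2)
  num <- sum(Rj^2) - b^2 * k * (k + 1)^2 / 4
  den <- A1 - b * k * (k + 1)^2 / 4
  if (den <= 0) return(0)  # all blocks fully tied
  (k - 1) * num / den
}

#' Friedman rank-sum test
#'
#' Tests for equal treatment effects across complete blocks using within-block
#' average ranks with the standard tie correction; the statistic is referred
#' to a chi-square distribution with k - 1 degrees of freedom. With
#' `exact = TRUE` an exact conditional p-value is also computed by enumerating
#' all within-block orderings (feasible only for small tables).
#'
#' Here the blocks are nesting years and the treatments foraging hotspots, but
#' the function accepts any complete two-way layout.
#'
#' @param x blocks x treatments matrix, or a [ContributionTable-class]
#'   (years become blocks)
#' @param exact also compute the exact permutation p-value
#' @param ... passed through by methods
#' @return a [FriedmanResult-class]
#' @export
setGeneric("friedmanRankTest",
           function(x, ...) standardGeneric("friedmanRankTest"))

#' @rdname friedmanRankTest
setMethod("friedmanRankTest", "matrix", function(x, exact = FALSE) {
  x <- checkRankTable(x)
  b <- nrow(x); k <- ncol(x)
  r <- blockRanks(x)
  stat <- friedmanStat(r)
  pExact <- NA_real_
  if (exact) {
    nPerm <- factorial(k)^b
    if (nPerm > 1e6)
      stop("exact enumeration infeasible: ", nPerm, " orderings",
           call. = FALSE)
    perms <- allPermutations(k)
    combos <- expand.grid(rep(list(seq_len(nrow(perms))), b))
    stats <- apply(combos, 1L, function(ix) {
      rp <- r
      for (i in seq_len(b)) rp[i, ] <- r[i, perms[ix[i], ]]
      friedmanStat(rp)
    })
    pExact <- mean(stats >= stat - 1e-12)
  }
  new("FriedmanResult", statistic = stat, df = k - 1,
      p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
      p.exact = pExact, rankSums = colSums(r), nBlocks = as.integer(b))
})

#' @rdname friedmanRankTest
setMethod("friedmanRankTest", "ContributionTable", function(x, exact = FALSE) {
  friedmanRankTest(t(x@values), exact = exact)
})

allPermutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Conover all-pairs post-hoc test after Friedman
#'
#' Conover's Friedman-type multiple comparison: with rank sums `R_j`,
#' `A1 = sum of squared within-block ranks` and `B1 = sum(R_j^2)/b`, the
#' pairwise statistic is `t = (R_i - R_j) / sqrt(2 b (A1 - B1) / ((b-1)(k-1)))`
#' on (b - 1)(k - 1) degrees of freedom. Two-sided p-values are adjusted with
#' the Benjamini-Hochberg false-discovery-rate step-up over the k(k-1)/2
#' distinct pairs, and a compact letter display at `alpha` is attached.
#'
#' @param x blocks x treatments matrix, or a [ContributionTable-class]
#' @param alpha significance level for the letter display
#' @param ... passed through by methods
#' @return a [PosthocResult-class]
#' @export
setGeneric("conoverPosthoc",
           function(x, ...) standardGeneric("conoverPosthoc"))

#' @rdname conoverPosthoc
setMethod("conoverPosthoc", "matrix", function(x, alpha = 0.05) {
  x <- checkRankTable(x)
  b <- nrow(x); k <- ncol(x)
  r <- blockRanks(x)
  Rj <- colSums(r)
  A1 <- sum(r^2)
  B1 <- sum(Rj^2) / b
  df <- (b - 1) * (k - 1)
  s2 <- 2 * b * (A1 - B1) / df
  tmat <- pmat <- matrix(NA_real_, k, k,
                         dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (s2 <= 1e-12) {
      # no residual rank variation: identical rank sums are indistinguishable,
      # any difference is perfectly consistent across blocks
      tt <- if (Rj[i] == Rj[j]) 0 else Inf * sign(Rj[i] - Rj[j])
    } else tt <- (Rj[i] - Rj[j]) / sqrt(s2)
    p <- 2 * stats::pt(-abs(tt), df)
    tmat[i, j] <- tmat[j, i] <- tt
    pmat[i, j] <- pmat[j, i] <- p
  }
  ut <- upper.tri(pmat)
  padj <- pmat
  padj[ut] <- stats::p.adjust(pmat[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  new("PosthocResult", statistic = tmat, p.raw = pmat, p.adjusted = padj,
      df = df, letters = letterDisplay(padj, alpha = alpha))
})

#' @rdname conoverPosthoc
setMethod("conoverPosthoc", "ContributionTable", function(x, alpha = 0.05) {
  conoverPosthoc(t(x@values), alpha = alpha)
})

#' Compact letter display
#'
#' Insert-and-absorb lettering: two treatments share a letter if and only if
#' their (adjusted) p-value is `>= alpha`. Letter sets are split on each
#' significant pair and subset-absorbed; letters are assigned in treatment
#' order, so the output is deterministic.
#'
#' @param p symmetric matrix of (adjusted) p-values, diagonal ignored
#' @param alpha significance level
#' @return character vector of letter strings, one per treatment
#' @export
letterDisplay <- function(p, alpha = 0.05) {
  k <- ncol(p)
  labs <- colnames(p)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(p[i, j]) || p[i, j] >= alpha) next
    nxt <- list()
    for (s in sets) {
      if (i %in% s && j %in% s)
        nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
      else nxt <- c(nxt, list(s))
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a != b && keep[a] && keep[b] && all(nxt[[a]] %in% nxt[[b]]) &&
          !(all(nxt[[b]] %in% nxt[[a]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- unique(lapply(nxt[keep], sort))
  }
  sets <- sets[order(vapply(sets, min, 0))]
  out <- vapply(seq_len(k), function(t)
    paste0(letters[which(vapply(sets, function(s) t %in% s, TRUE))],
           collapse = ""), "")
  stats::setNames(out, labs)
}
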