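## Exact contingency statistics and verification comparisons.

#' Exact Freeman–Halton test for an r x 2 contingency table
#'
#' Fisher's exact test extended to r treatments by complete enumeration:
#' all tables sharing the observed row and column margins are generated,
#' and the two-sided p-value sums the multivariate hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (relative tie tolerance 1e-7). For a 2 x 2 input
#' this reduces to the classical hypergeometric tail construction. An
#' enumeration guard refuses tables with more than `guard` candidate
#' configurations.
#'
#' @param table Matrix (or data frame) of non-negative integer counts with
#'   at least 2 rows and exactly 2 columns (e.g. alive/dead per treatment).
#' @param guard Maximum number of candidate tables.
#' @return List: `p.value`, `n.tables` enumerated, and `total.prob`, the
#'   summed probability over the full enumeration (equals 1 up to rounding
#'   error — a completeness check).
#' @export
#' @examples
#' fisherExactRxC(rbind(c(3, 1), c(1, 3)))$p.value  # 34/70
fisherExactRxC <- function(table, guard = 1e7) {
  tab <- as.matrix(table)
  if (!is.numeric(tab) || any(is.na(tab)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("table must contain non-negative integer counts")
  if (ncol(tab) != 2 || nrow(tab) < 2)
    stop("table must be r x 2 with r >= 2")
  storage.mode(tab) <- "integer"
  res <- .freemanHaltonCpp(tab, tol = 1e-7, guard = guard)
  list(p.value = res$p, n.tables = res$n_tables, total.prob = res$total)
}

#' Summary descriptors
#'
#' Arithmetic mean, sample standard deviation (n - 1) and n, the format in
#' which development times and brood sizes are tabulated. The SD of a
#' single value is undefined and reported as `NA`.
#'
#' @param values Numeric vector (length >= 1).
#' @return Named numeric vector `(mean, sd, n)`.
#' @export
summaryDescriptors <- function(values) {
  if (length(values) < 1) stop("empty input")
  c(mean = mean(values), sd = if (length(values) > 1) sd(values) else
    NA_real_, n = length(values))
}

#' Copepodite-to-naupliar duration ratio
#'
#' The ratio of mean copepodite to mean naupliar development time; its
#' constancy across temperatures is termed equiproportionality.
#'
#' @param meanC,meanN Mean copepodite and naupliar durations, days.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' dcDnRatio(12.31, 9.52)  # 1.29
dcDnRatio <- function(meanC, meanN) meanC / meanN

#' One-sample t-test against a theoretical value
#'
#' One-sided one-sample t-test of a simulated sample against a theoretical
#' function value, the comparison used for the reproduction-test
#' verification. The direction of the one-sided test is not uniquely
#' determined by a statement like "one-sided, alpha = 5%"; here
#' `side = "auto"` tests in the direction of the observed deviation (the
#' conservative reading — the reported p is the smaller of the two
#' one-sided p-values), and both one-sided p-values are returned so either
#' convention can be read off. A zero-variance sample equal to the
#' theoretical value is a degenerate pass (p = 1, flagged); zero variance
#' with a non-zero deviation is a degenerate fail (p = 0, flagged).
#'
#' @param sample Numeric sample (n >= 2).
#' @param mu Theoretical value.
#' @param side `"auto"`, `"greater"` or `"less"`.
#' @return List: `p.value`, `side`, `p.greater`, `p.less`, `estimate`,
#'   `degenerate`.
#' @export
#' @examples
#' set.seed(1)
#' oneSampleT(rnorm(50, 4.04, 0.8), 4.04)$p.value
oneSampleT <- function(sample, mu, side = c("auto", "greater", "less")) {
  side <- match.arg(side)
  sample <- sample[!is.na(sample)]
  if (length(sample) < 2) stop("need at least 2 observations")
  est <- mean(sample)
  if (sd(sample) == 0) {
    degenerate_pass <- isTRUE(all.equal(est, mu))
    return(list(p.value = if (degenerate_pass) 1 else 0,
                side = side, p.greater = NA_real_, p.less = NA_real_,
                estimate = est, degenerate = TRUE))
  }
  pg <- t.test(sample, mu = mu, alternative = "greater")$p.value
  pl <- t.test(sample, mu = mu, alternative = "less")$p.value
  if (side == "auto") side <- if (est >= mu) "greater" else "less"
  list(p.value = if (side == "greater") pg else pl, side = side,
       p.greater = pg, p.less = pl, estimate = est, degenerate = FALSE)
}

#' Coverage of observations by a Monte-Carlo confidence band
#'
#' Fraction of observed day/stage counts lying inside the percentile band
#' of a [MonteCarloSummary-class].
#'
#' @param summary A [MonteCarloSummary-class].
#' @param observations Data frame with columns `day` (0-based, within the
#'   simulated range), `stage` (one of `"nauplii"`, `"copepodites"`,
#'   `"adults"`, `"dead"`) and `count`.
#' @return List: `coverage` (fraction inside the band, `NA` for an empty
#'   observation set, flagged) and `n`.
#' @export
ciCoverage <- function(summary, observations) {
  stopifnot(is(summary, "MonteCarloSummary"))
  if (nrow(observations) == 0)
    return(list(coverage = NA_real_, n = 0L, flag = "empty observation set"))
  maxDay <- nrow(summary@mean) - 1L
  if (any(observations$day < 0 | observations$day > maxDay))
    stop("observation days outside the simulated range")
  if (any(!observations$stage %in% colnames(summary@mean)))
    stop("unknown stage name in observations")
  i <- cbind(observations$day + 1L,
             match(observations$stage, colnames(summary@mean)))
  inside <- observations$count >= summary@lower[i] &
    observations$count <= summary@upper[i]
  list(coverage = mean(inside), n = nrow(observations), flag = NULL)
}
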