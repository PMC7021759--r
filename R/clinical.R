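#' Build a 2x2 contingency table of mutation status by a two-level grouping
#'
#' Tallies a per-patient cohort into a 2x2 table with one row per grouping
#' level and columns (mutant, non-mutant).  Rows with missing values in
#' either column are excluded and their count reported as an attribute.
#'
#' @param cohort data frame with one row per patient.
#' @param mutation name of the logical mutation-status column.
#' @param grouping name of the grouping column (exactly 2 levels after
#'   dropping missing values), or a factor to control row order.
#' @return A 2x2 integer matrix with attributes `n_missing` and
#'   `percent` (row-wise mutant percentage).
#' @export
build_contingency <- function(cohort, mutation = "mutant",
                              grouping = "stratum") {
  g <- cohort[[grouping]]
  m <- cohort[[mutation]]
  miss <- is.na(g) | is.na(m)
  if (any(miss)) {
    warning(sum(miss), " patient(s) with missing values excluded")
    g <- g[!miss]; m <- m[!miss]
  }
  if (!is.factor(g)) g <- factor(g, levels = unique(g))
  if (nlevels(g) != 2)
    stop("grouping must have exactly 2 levels, got ", nlevels(g))
  tab <- matrix(0L, 2, 2,
                dimnames = list(levels(g), c("mutant", "non_mutant")))
  for (i in 1:2) {
    sel <- g == levels(g)[i]
    tab[i, 1] <- sum(m[sel])
    tab[i, 2] <- sum(!m[sel])
  }
  if (!nrow(cohort)) warning("empty cohort; all-zero table")
  attr(tab, "n_missing") <- sum(miss)
  attr(tab, "percent") <- tab[, 1] / pmax(1, rowSums(tab)) * 100
  tab
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Standard two-sided definition: the sum of hypergeometric point
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one.  A table with a zero margin is degenerate and
#' returns p = 1.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A list: `p` and `degenerate` (logical).
#' @export
fisher_two_tailed <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(table)$p.value, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A list: `statistic` (1 df chi-square) and `p`.
#' @export
chi_square_test <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0))
    stop("zero expected count; use fisher_two_tailed()")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Choose between Fisher and chi-square for a 2x2 table
#'
#' Uses the classical expected-count rule: Fisher when any expected cell
#' count is below 5, chi-square otherwise.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return `"fisher"` or `"chi_square"`.
#' @export
select_test <- function(table) {
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) "fisher" else "chi_square"
}

#' Cochran-Mantel-Haenszel test across 2x2 strata
#'
#' Mantel-Haenszel chi-square (1 df, no continuity correction) with the MH
#' common odds-ratio estimate.  All-zero strata are dropped with a warning.
#' With a single stratum it reduces to the unstratified MH statistic
#' (which carries the N-1 finite-population factor relative to Pearson's
#' chi-square).
#'
#' @param strata list of 2x2 matrices.
#' @return A list: `statistic`, `p`, `common_odds_ratio`.
#' @export
cmh_test <- function(strata) {
  stopifnot(length(strata) >= 1)
  keep <- vapply(strata, function(s) sum(s) > 0, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " all-zero stratum/strata dropped")
    strata <- strata[keep]
  }
  if (!length(strata)) stop("no usable strata")
  if (length(strata) == 1) {
    # mantelhaen.test() needs >= 2 strata; the single-stratum MH statistic
    # has the standard closed form with the finite-population variance
    s <- strata[[1]]
    n <- sum(s)
    a <- s[1, 1]
    e <- rowSums(s)[1] * colSums(s)[1] / n
    v <- prod(rowSums(s)) * prod(colSums(s)) / (n^2 * (n - 1))
    stat <- if (v == 0) 0 else unname((a - e)^2 / v)
    or <- (s[1, 1] * s[2, 2]) / (s[1, 2] * s[2, 1])
    return(list(statistic = stat,
                p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                common_odds_ratio = unname(or)))
  }
  arr <- array(unlist(strata), dim = c(2, 2, length(strata)))
  res <- stats::mantelhaen.test(arr, correct = FALSE)
  list(statistic = unname(res$statistic), p = res$p.value,
       common_odds_ratio = unname(res$estimate))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from beta quantiles; `k = 0` gives a lower bound of
#' 0 and `k = n` an upper bound of 1.
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Association p-value for one clinical classification of the study cohort
#'
#' Builds the 2x2 table for a classification from the packaged cohort
#' counts (via [table1_cohort()]) and applies either the pinned test
#' recorded in [table1_counts()] (`test = "pinned"`), the expected-count
#' selection rule (`"auto"`), or a named test.
#'
#' @param classification a classification name from [table1_counts()].
#' @param test `"pinned"`, `"auto"`, `"fisher"` or `"chi_square"`.
#' @param seed passed to [table1_cohort()] (margins are seed-invariant).
#' @return A list: `table`, `test`, `p`.
#' @export
table1_association <- function(classification,
                               test = c("pinned", "auto", "fisher",
                                        "chi_square"),
                               seed = 1) {
  test <- match.arg(test)
  cohort <- table1_cohort(classification, seed = seed)
  tc <- table1_counts()
  lev <- tc$level[tc$classification == classification]
  cohort$stratum <- factor(cohort$stratum, levels = lev)
  tab <- build_contingency(cohort)
  if (test == "pinned")
    test <- tc$test[tc$classification == classification][1]
  else if (test == "auto")
    test <- select_test(tab)
  p <- if (test == "fisher") fisher_two_tailed(tab)$p
       else chi_square_test(tab)$p
  list(table = tab, test = test, p = p)
}
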