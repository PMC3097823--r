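#' Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Two-sample rank-sum test, exact when the combined sample size is at most
#' 25 and tie-free, otherwise the normal approximation with tie correction
#' (and continuity correction). Thin wrapper around [stats::wilcox.test]
#' with the switching rule fixed so results are reproducible.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)) # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0 || length(b) == 0) abort("samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 25) && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value
  )
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests H0: sample `a` is stochastically less than or equal to sample `b`,
#' against the alternative that `a` tends to larger values. The statistic
#' is the maximal amount by which the empirical CDF of `a` falls below that
#' of `b`; the p-value is asymptotic (ties are common in edge-weight data,
#' where no exact p exists).
#'
#' @param a,b Numeric samples (non-empty).
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_one_sided <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("samples must be non-empty")
  res <- suppressWarnings(
    stats::ks.test(a, b, alternative = "less", exact = FALSE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' G-test of independence for a 2x2 table
#'
#' Likelihood-ratio test `G = 2 * sum(O * ln(O / E))` with expected counts
#' from the margins, compared to a chi-square distribution with 1 degree
#' of freedom. Zero observed cells contribute 0 to the sum.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @return A list with `statistic` (G) and `p_value`.
#' @examples
#' # borrowed vs not, nouns vs verbs
#' g_test_2x2(matrix(c(503, 384, 450, 316), 2, byrow = TRUE))
#' @export
g_test_2x2 <- function(table) {
  O <- as.matrix(table)
  if (!all(dim(O) == c(2L, 2L))) abort("table must be 2x2")
  if (any(O < 0)) abort("counts must be non-negative")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) abort("table has a zero margin")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  list(statistic = G, p_value = pchisq(G, df = 1, lower.tail = FALSE))
}

#' Fraction of interquartile range between two size distributions
#'
#' `(median(ancestral) - median(contemporary)) / IQR(contemporary)`:
#' a scale-free summary of how far ancestral inventory sizes sit from the
#' contemporary distribution. Positive when ancestral inventories are
#' larger; quartiles use linear interpolation (R's default type 7).
#'
#' @param ancestral,contemporary Numeric samples.
#' @return The fraction (a single number).
#' @export
iqr_fraction <- function(ancestral, contemporary) {
  iqr <- stats::IQR(contemporary, type = 7)
  if (iqr == 0) abort("contemporary IQR is zero; fraction undefined")
  (median(ancestral) - median(contemporary)) / iqr
}
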