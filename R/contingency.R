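#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of all tables
#' (with the observed margins fixed) whose probability does not exceed the
#' observed table's; both one-sided p-values are reported alongside. Any
#' zero margin gives p = 1 (only one table is possible). The computation is
#' delegated to [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble with `p_two_sided`, `p_less`, `p_greater`,
#'   `odds_ratio` (conditional MLE).
#' @examples
#' fisher_exact(matrix(c(5, 1, 1, 5), nrow = 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == floor(table)))
  two <- stats::fisher.test(table, alternative = "two.sided")
  tibble(
    p_two_sided = two$p.value,
    p_less = stats::fisher.test(table, alternative = "less")$p.value,
    p_greater = stats::fisher.test(table, alternative = "greater")$p.value,
    odds_ratio = unname(two$estimate)
  )
}

#' Pearson chi-square test for a 2xk table
#'
#' Standard Pearson statistic without continuity correction;
#' `df = k - 1` for a 2xk table. A zero expected count is an error
#' suggesting [fisher_exact()].
#'
#' @param table 2xk matrix of non-negative counts.
#' @return One-row tibble with `chi2`, `df`, `p`, and
#'   `min_expected` (useful for the expected-count-below-5 switch).
#' @examples
#' pearson_chi2(matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    abort("Zero expected count; use fisher_exact() instead.")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble(
    chi2 = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value, min_expected = min(expected)
  )
}
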