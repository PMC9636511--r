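#' Hardy-Weinberg equilibrium chi-square test
#'
#' Tests observed genotype counts against the expected proportions
#' `p^2 : 2pq : q^2` with a one-degree-of-freedom chi-square statistic and
#' no continuity correction. Vectorized over rows of `counts`. A
#' monomorphic variant (all one homozygote class) has no testable
#' equilibrium and is returned flagged, not as an error.
#'
#' @param counts Data frame with columns `n_ref_hom`, `n_het`, `n_alt_hom`
#'   (e.g. from [genotype_counts()]).
#' @return Tibble, one row per input row: `n`, `alt_freq`, `expected_*`,
#'   `chi2`, `df`, `p`, `defined`, `note`.
#' @examples
#' hwe_test(tibble::tibble(n_ref_hom = 73, n_het = 111, n_alt_hom = 25))
#' @export
hwe_test <- function(counts) {
  counts <- as_tibble(counts)
  req <- c("n_ref_hom", "n_het", "n_alt_hom")
  if (!all(req %in% names(counts))) {
    abort("`counts` needs columns n_ref_hom, n_het, n_alt_hom.")
  }
  purrr::pmap_dfr(counts[req], function(n_ref_hom, n_het, n_alt_hom) {
    n <- n_ref_hom + n_het + n_alt_hom
    if (n < 1) abort("HWE test needs at least one genotyped sample.")
    p_ref <- (2 * n_ref_hom + n_het) / (2 * n)
    q_alt <- 1 - p_ref
    base <- tibble(n = n, alt_freq = q_alt)
    if (p_ref %in% c(0, 1)) {
      return(mutate(base, expected_ref_hom = NA_real_,
                    expected_het = NA_real_, expected_alt_hom = NA_real_,
                    chi2 = NA_real_, df = 1L, p = NA_real_,
                    defined = FALSE, note = "monomorphic"))
    }
    e <- c(n * p_ref^2, 2 * n * p_ref * q_alt, n * q_alt^2)
    o <- c(n_ref_hom, n_het, n_alt_hom)
    chi2 <- sum((o - e)^2 / e)
    mutate(base,
           expected_ref_hom = e[1], expected_het = e[2],
           expected_alt_hom = e[3], chi2 = chi2, df = 1L,
           p = pchisq(chi2, df = 1, lower.tail = FALSE),
           defined = TRUE, note = NA_character_)
  })
}

#' Allele counts from genotype counts
#'
#' Reference-allele count `2 * n_ref_hom + n_het` and alternate-allele count
#' `2 * n_alt_hom + n_het`; the "allelic" row of a genetic-model table.
#' Vectorized over rows.
#'
#' @inheritParams hwe_test
#' @return Tibble with `n_ref_alleles`, `n_alt_alleles`.
#' @examples
#' allele_counts(tibble::tibble(n_ref_hom = 72, n_het = 102, n_alt_hom = 31))
#' @export
allele_counts <- function(counts) {
  counts <- as_tibble(counts)
  tibble(
    n_ref_alleles = 2L * counts$n_ref_hom + counts$n_het,
    n_alt_alleles = 2L * counts$n_alt_hom + counts$n_het
  )
}
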