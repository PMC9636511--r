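#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Core LD algebra shared by the phased and EM-based estimators. With
#' alternate-allele haplotype frequency `f11` and alternate-allele
#' frequencies `p1`, `p2`:
#' `D = f11 - p1 p2`;
#' `D' = D / Dmax`, `Dmax = min(p1 (1-p2), (1-p1) p2)` for `D > 0` and
#' `min(p1 p2, (1-p1)(1-p2))` for `D < 0`;
#' `r2 = D^2 / (p1 (1-p1) p2 (1-p2))`.
#' A monomorphic locus leaves all three undefined; the result is flagged
#' rather than propagating NaN.
#'
#' @param f11,f10,f01,f00 Haplotype frequencies (alt/alt, alt/ref, ref/alt,
#'   ref/ref), summing to 1.
#' @param n_chromosomes Number of chromosomes behind the estimate.
#' @return One-row tibble with `p1`, `p2`, the four haplotype frequencies,
#'   `d`, `d_prime`, `r2`, `n_chromosomes`, `defined` and `note`.
#' @export
ld_stats <- function(f11, f10, f01, f00, n_chromosomes = NA_integer_) {
  tot <- f11 + f10 + f01 + f00
  if (abs(tot - 1) > 1e-6) abort("Haplotype frequencies must sum to 1.")
  p1 <- f11 + f10
  p2 <- f11 + f01
  base <- tibble(
    p1 = p1, p2 = p2,
    freq_11 = f11, freq_10 = f10, freq_01 = f01, freq_00 = f00,
    n_chromosomes = as.integer(n_chromosomes)
  )
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    return(mutate(base, d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                  defined = FALSE, note = "monomorphic locus"))
  }
  d <- f11 - p1 * p2
  d_max <- if (d > 0) {
    min(p1 * (1 - p2), (1 - p1) * p2)
  } else {
    min(p1 * p2, (1 - p1) * (1 - p2))
  }
  d_prime <- if (d == 0) 0 else d / d_max
  r2 <- d^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  mutate(base, d = d, d_prime = d_prime, r2 = r2,
         defined = TRUE, note = NA_character_)
}

#' Pairwise LD from a phased panel
#'
#' Counts the four haplotype classes directly from the phased allele columns
#' of two variants and applies [ld_stats()]. Convention: allele 1 is the
#' alternate allele at each locus.
#'
#' @param panel A [haplotype_panel()].
#' @param v1,v2 Variant ids or row indices.
#' @return One-row tibble as [ld_stats()], prefixed with `id1`, `id2`.
#' @examples
#' panel <- simulate_panel(simulation_spec(n_individuals = 100, n_variants = 2,
#'   target_ld = list(list(pair = c(1, 2), r2 = 0.8)), rng_seed = 1))
#' ld_from_phased(panel, 1, 2)
#' @export
ld_from_phased <- function(panel, v1, v2) {
  i <- panel_index(panel, v1)
  j <- panel_index(panel, v2)
  x <- panel$alleles[i, ]
  y <- panel$alleles[j, ]
  n <- length(x)
  if (n < 2) abort("LD needs at least 2 chromosomes.")
  f11 <- mean(x == 1L & y == 1L)
  f10 <- mean(x == 1L & y == 0L)
  f01 <- mean(x == 0L & y == 1L)
  f00 <- mean(x == 0L & y == 0L)
  out <- ld_stats(f11, f10, f01, f00, n_chromosomes = n)
  dplyr::bind_cols(
    tibble(id1 = panel$variants$id[i], id2 = panel$variants$id[j]), out
  )
}

#' All-pairs LD table from a phased panel
#'
#' One row per unordered variant pair on the same chromosome; the shape
#' used for D'/r-squared summaries over a region.
#'
#' @param panel A [haplotype_panel()].
#' @return Tibble of class `mirtld_ld_table` with coordinates and LD
#'   statistics per pair.
#' @export
ld_pairwise <- function(panel) {
  v <- panel$variants
  pairs <- tidyr::expand_grid(i = seq_len(nrow(v)), j = seq_len(nrow(v))) |>
    filter(.data$i < .data$j, v$chrom[.data$i] == v$chrom[.data$j])
  out <- purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    mutate(ld_from_phased(panel, i, j),
           chrom = v$chrom[i], pos1 = v$pos[i], pos2 = v$pos[j],
           .before = 1)
  })
  class(out) <- c("mirtld_ld_table", class(out))
  out
}
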