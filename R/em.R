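#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes. All joint genotype classes except the double heterozygote are
#' phase-unambiguous and contribute fixed haplotype counts; the double
#' heterozygote is split between the coupling (alt-alt / ref-ref) and
#' repulsion (alt-ref / ref-alt) phases in proportion to
#' `f11 f00 : f10 f01` at the current estimate (E-step), after which the
#' expected haplotype counts are renormalized (M-step). Initialization is at
#' linkage-equilibrium products of the observed allele frequencies; if the
#' two phase assignments are exactly equally likely there, the algorithm
#' stays at that symmetric fixed point and the result carries a
#' `"symmetric likelihood"` note.
#'
#' @param geno A [genotype_matrix()].
#' @param v1,v2 Variant ids or column indices.
#' @param tol Convergence tolerance on the maximum frequency change.
#' @param max_iter Iteration cap; exceeding it sets `converged = FALSE`.
#' @return Object of class `mirtld_em` with elements `hap_freqs` (named
#'   `f11`, `f10`, `f01`, `f00`: alt/alt, alt/ref, ref/alt, ref/ref),
#'   `log_likelihood`, `trace` (per-iteration log-likelihood),
#'   `n_iterations`, `converged`, `n_samples`, `n_double_het`, `note`.
#' @export
em_two_locus <- function(geno, v1, v2, tol = 1e-10, max_iter = 1000L) {
  stopifnot(tol > 0, max_iter >= 1)
  i <- geno_column(geno, v1)
  j <- geno_column(geno, v2)
  g1 <- geno$codes[, i]
  g2 <- geno$codes[, j]
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]
  g2 <- g2[keep]
  n <- length(g1)
  if (n < 1) abort("No samples typed at both variants.")
  # 3x3 joint genotype counts, rows g1, cols g2
  cnt <- matrix(0, 3, 3)
  for (k in seq_len(n)) cnt[g1[k] + 1, g2[k] + 1] <- cnt[g1[k] + 1, g2[k] + 1] + 1
  n_dh <- cnt[2, 2]
  # unambiguous haplotype counts contributed by each non-double-het class
  # haplotypes indexed (11, 10, 01, 00) by alt alleles carried
  base <- c(
    f11 = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    f10 = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    f01 = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    f00 = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  )
  p1 <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / (2 * n)
  p2 <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / (2 * n)
  f <- c(f11 = p1 * p2, f10 = p1 * (1 - p2),
         f01 = (1 - p1) * p2, f00 = (1 - p1) * (1 - p2))
  ll_fun <- function(f) em_loglik(cnt, f)
  trace <- ll_fun(f)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- f["f11"] * f["f00"] + f["f10"] * f["f01"]
    w <- if (n_dh > 0 && denom > 0) f["f11"] * f["f00"] / denom else 0.5
    counts <- base + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    trace <- c(trace, ll_fun(f))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  note <- NA_character_
  if (n_dh > 0 && abs(f["f11"] * f["f00"] - f["f10"] * f["f01"]) < 1e-12) {
    note <- "symmetric likelihood"
  }
  structure(
    list(
      id1 = geno$variants$id[i], id2 = geno$variants$id[j],
      hap_freqs = f, log_likelihood = unname(trace[length(trace)]),
      trace = unname(trace), n_iterations = iter, converged = converged,
      n_samples = n, n_double_het = unname(n_dh), note = note
    ),
    class = "mirtld_em"
  )
}

# multinomial log-likelihood of the 3x3 genotype counts given hap freqs
em_loglik <- function(cnt, f) {
  probs <- matrix(0, 3, 3)
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  fv <- c(f[["f11"]], f[["f10"]], f[["f01"]], f[["f00"]])
  for (a in 1:4) {
    for (b in 1:4) {
      g <- haps[a, ] + haps[b, ]
      probs[g[1] + 1, g[2] + 1] <- probs[g[1] + 1, g[2] + 1] + fv[a] * fv[b]
    }
  }
  sum(cnt[cnt > 0] * log(probs[cnt > 0]))
}

#' @export
print.mirtld_em <- function(x, ...) {
  cat(sprintf("<two-locus EM: %s x %s, n = %d (%d double het)>\n",
              x$id1, x$id2, x$n_samples, x$n_double_het))
  print(round(x$hap_freqs, 5))
  cat(sprintf("logLik %.4f after %d iteration(s); converged: %s\n",
              x$log_likelihood, x$n_iterations, x$converged))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @describeIn em_two_locus One row per haplotype with its frequency.
#' @param x A `mirtld_em` object.
#' @param ... Unused.
#' @export
tidy.mirtld_em <- function(x, ...) {
  tibble(
    haplotype = c("alt/alt", "alt/ref", "ref/alt", "ref/ref"),
    frequency = unname(x$hap_freqs)
  )
}

#' @describeIn em_two_locus One-row fit summary.
#' @export
glance.mirtld_em <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood, n_iterations = x$n_iterations,
    converged = x$converged, n_samples = x$n_samples,
    n_double_het = x$n_double_het
  )
}

#' LD statistics from unphased genotypes
#'
#' Runs [em_two_locus()] and applies [ld_stats()] to the estimated
#' haplotype frequencies; the route used for study subjects, whose phase
#' is unobserved.
#'
#' @inheritParams em_two_locus
#' @return One-row tibble as [ld_from_phased()], plus `converged`.
#' @export
ld_from_unphased <- function(geno, v1, v2, tol = 1e-10, max_iter = 1000L) {
  fit <- em_two_locus(geno, v1, v2, tol = tol, max_iter = max_iter)
  f <- fit$hap_freqs
  out <- ld_stats(f[["f11"]], f[["f10"]], f[["f01"]], f[["f00"]],
                  n_chromosomes = 2L * fit$n_samples)
  dplyr::bind_cols(tibble(id1 = fit$id1, id2 = fit$id2), out,
                   tibble(converged = fit$converged))
}
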