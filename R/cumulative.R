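#' Cumulative two-locus genotype and haplotype frequencies by group
#'
#' For each sample group: the joint genotype frequency over the nine
#' two-locus classes (denominator = samples typed at BOTH variants), and the
#' EM-estimated haplotype frequencies from [em_two_locus()]. Pairwise group
#' comparisons are made per class (in-class vs not) by Pearson chi-square,
#' switching to Fisher's exact test when any expected count falls below 5.
#' Haplotype-class comparisons use the EM frequencies scaled to rounded
#' chromosome counts.
#'
#' @param geno A [genotype_matrix()].
#' @param v1,v2 Variant ids or column indices.
#' @param groups Named list of sample-id vectors, or a vector/factor of
#'   group labels aligned with `geno$samples`.
#' @return Object of class `mirtld_cumulative`: list with `frequencies`
#'   (long tibble: `group`, `type`, `class`, `count`, `n`, `frequency`) and
#'   `comparisons` (tibble of pairwise per-class tests).
#' @export
cumulative_genotypes <- function(geno, v1, v2, groups) {
  i <- geno_column(geno, v1)
  j <- geno_column(geno, v2)
  if (!is.list(groups)) {
    groups <- split(geno$samples, groups)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be named.")
  }
  ref1 <- geno$variants$ref[i]; alt1 <- geno$variants$alt[i]
  ref2 <- geno$variants$ref[j]; alt2 <- geno$variants$alt[j]
  geno_classes <- as.vector(outer(
    genotype_label(0:2, ref1, alt1), genotype_label(0:2, ref2, alt2),
    function(a, b) paste0(a, "/", b)))
  hap_classes <- as.vector(outer(c(alt1, ref1), c(alt2, ref2), paste, sep = "/"))

  per_group <- purrr::imap(groups, function(ids, name) {
    idx <- match(ids, geno$samples)
    if (anyNA(idx)) abort(paste0("Unknown sample id(s) in group ", name))
    g1 <- geno$codes[idx, i]
    g2 <- geno$codes[idx, j]
    keep <- !is.na(g1) & !is.na(g2)
    n <- sum(keep)
    if (n == 0) {
      warn(paste0("Group '", name, "' has no complete cases; excluded."))
      return(NULL)
    }
    cls <- paste0(genotype_label(g1[keep], ref1, alt1), "/",
                  genotype_label(g2[keep], ref2, alt2))
    cnt <- table(factor(cls, levels = geno_classes))
    sub <- genotype_matrix(geno$samples[idx][keep],
                           geno$variants[c(i, j), ],
                           geno$codes[idx, , drop = FALSE][keep, c(i, j),
                                                          drop = FALSE])
    em <- em_two_locus(sub, 1, 2)
    # hap order (f11, f10, f01, f00) = (alt/alt, alt/ref, ref/alt, ref/ref)
    hf <- unname(em$hap_freqs[c("f11", "f10", "f01", "f00")])
    names(hf) <- c(paste0(alt1, "/", alt2), paste0(alt1, "/", ref2),
                   paste0(ref1, "/", alt2), paste0(ref1, "/", ref2))
    list(
      freq = bind_rows(
        tibble(group = name, type = "genotype", class = names(cnt),
               count = as.integer(cnt), n = n,
               frequency = as.numeric(cnt) / n),
        tibble(group = name, type = "haplotype", class = names(hf),
               count = as.integer(round(unname(hf) * 2 * n)), n = 2L * n,
               frequency = unname(hf))
      )
    )
  })
  per_group <- purrr::compact(per_group)
  if (length(per_group) < 1) abort("No group has complete-case samples.")
  freq <- purrr::map_dfr(per_group, "freq")

  group_names <- unique(freq$group)
  comparisons <- tibble()
  if (length(group_names) >= 2) {
    pairs <- utils::combn(group_names, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(gp) {
      purrr::map_dfr(c("genotype", "haplotype"), function(ty) {
        fa <- filter(freq, .data$group == gp[1], .data$type == ty)
        fb <- filter(freq, .data$group == gp[2], .data$type == ty)
        purrr::map_dfr(unique(fa$class), function(cl) {
          a_in <- fa$count[fa$class == cl]; a_n <- fa$n[1]
          b_in <- fb$count[fb$class == cl]; b_n <- fb$n[1]
          tab <- matrix(c(a_in, a_n - a_in, b_in, b_n - b_in), nrow = 2,
                        byrow = TRUE)
          expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
          if (any(expected < 5)) {
            p <- fisher_exact(tab)$p_two_sided
            test <- "fisher_exact"
          } else {
            p <- pearson_chi2(tab)$p
            test <- "pearson_chi2"
          }
          or <- crude_or(tab)
          tibble(group_a = gp[1], group_b = gp[2], type = ty, class = cl,
                 count_a = a_in, n_a = a_n, count_b = b_in, n_b = b_n,
                 test = test, p = p, or_point = or$or_point,
                 ci_low = or$ci_low, ci_high = or$ci_high)
        })
      })
    })
  }
  structure(list(frequencies = freq, comparisons = comparisons,
                 id1 = geno$variants$id[i], id2 = geno$variants$id[j]),
            class = "mirtld_cumulative")
}

#' @export
print.mirtld_cumulative <- function(x, ...) {
  cat(sprintf("<cumulative genotypes/haplotypes: %s / %s>\n", x$id1, x$id2))
  wide <- tidyr::pivot_wider(
    select(x$frequencies, "group", "type", "class", "frequency"),
    names_from = "group", values_from = "frequency")
  print(wide, n = 20)
  invisible(x)
}

#' @describeIn cumulative_genotypes Long frequency table.
#' @param x A `mirtld_cumulative` object.
#' @param ... Unused.
#' @export
tidy.mirtld_cumulative <- function(x, ...) x$frequencies
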