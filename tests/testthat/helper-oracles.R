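# Independent brute-force oracles and small fixture builders.

# --- fixtures -------------------------------------------------------------

toy_variants <- function(n, chrom = "1", pos = NULL) {
  tibble::tibble(
    id = sprintf("v%03d", seq_len(n)),
    chrom = chrom,
    pos = if (is.null(pos)) as.integer(seq(100, by = 100, length.out = n))
          else as.integer(pos),
    ref = "A", alt = "G"
  )
}

# panel built from explicit haplotype class counts (n11, n10, n01, n00)
panel_from_hap_counts <- function(n11, n10, n01, n00) {
  x <- c(rep(1L, n11 + n10), rep(0L, n01 + n00))
  y <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  haplotype_panel(toy_variants(2), rbind(x, y))
}

# genotype matrix straight from a code matrix (samples x variants)
geno_from_codes <- function(codes) {
  codes <- as.matrix(codes)
  genotype_matrix(sprintf("S%03d", seq_len(nrow(codes))),
                  toy_variants(ncol(codes)), codes)
}

write_phased_vcf_text <- function(path, lines_gt,
                                  pos = c(100L, 200L),
                                  ids = c("rs1", "rs2"),
                                  alt = c("G", "G")) {
  samples <- paste0("SAM", seq_along(strsplit(lines_gt[[1]], " ")[[1]]))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(lines_gt), function(i) {
    paste(c("1", pos[i], ids[i], "A", alt[i], ".", "PASS", ".", "GT",
            strsplit(lines_gt[[i]], " ")[[1]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# --- EM oracle: grid maximizer of the multinomial likelihood --------------

# closed-form genotype-class probabilities given haplotype frequencies
oracle_geno_probs <- function(f11, f10, f01, f00) {
  cbind(
    p00 = f00^2, p01 = 2 * f00 * f01, p02 = f01^2,
    p10 = 2 * f00 * f10, p11 = 2 * f11 * f00 + 2 * f10 * f01,
    p12 = 2 * f01 * f11,
    p20 = f10^2, p21 = 2 * f10 * f11, p22 = f11^2
  )
}

oracle_ll <- function(f11, f10, f01, f00, cnt) {
  # cnt: 3x3 matrix, rows genotype at locus 1, cols locus 2
  n <- as.vector(t(cnt)) # order 00,01,02,10,11,12,20,21,22
  probs <- oracle_geno_probs(f11, f10, f01, f00)
  lp <- log(pmax(probs, 1e-300))
  drop(lp %*% n)
}

# coarse simplex scan then 1e-3 refinement around the coarse optimum
oracle_em_grid <- function(cnt, coarse = 0.01, fine = 1e-3) {
  scan <- function(f11s, f10s, f01s) {
    g <- expand.grid(f11 = f11s, f10 = f10s, f01 = f01s)
    g$f00 <- 1 - g$f11 - g$f10 - g$f01
    g <- g[g$f00 >= -1e-12, , drop = FALSE]
    g$f00 <- pmax(g$f00, 0)
    g$ll <- oracle_ll(g$f11, g$f10, g$f01, g$f00, cnt)
    g[which.max(g$ll), ]
  }
  s <- seq(0, 1, by = coarse)
  best <- scan(s, s, s)
  w <- 1.5 * coarse
  ref <- function(x) seq(max(0, x - w), min(1, x + w), by = fine)
  best <- scan(ref(best$f11), ref(best$f10), ref(best$f01))
  c(f11 = best$f11, f10 = best$f10, f01 = best$f01, f00 = best$f00)
}

geno_joint_counts <- function(geno, v1 = 1, v2 = 2) {
  g1 <- geno$codes[, v1]
  g2 <- geno$codes[, v2]
  keep <- !is.na(g1) & !is.na(g2)
  table(factor(g1[keep], 0:2), factor(g2[keep], 0:2))
}

# --- LD / proxy oracles ---------------------------------------------------

oracle_r2 <- function(panel, i, j) {
  stats::cor(panel$alleles[i, ], panel$alleles[j, ])^2
}

oracle_proxy_scan <- function(index_id, panel, r2_threshold, window) {
  v <- panel$variants
  i <- match(index_id, v$id)
  hits <- character()
  for (j in seq_len(nrow(v))) {
    if (v$chrom[j] != v$chrom[i]) next
    if (abs(v$pos[j] - v$pos[i]) > window) next
    r2 <- if (j == i) 1 else oracle_r2(panel, i, j)
    if (!is.na(r2) && r2 >= r2_threshold) hits <- c(hits, v$id[j])
  }
  sort(hits)
}

# --- interval oracle: O(n*m) double loop ----------------------------------

oracle_intersect <- function(variants, sites, flank) {
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    for (s in seq_len(nrow(sites))) {
      if (variants$chrom[v] != sites$chrom[s]) next
      lo <- max(0, sites$start[s] - flank)
      hi <- sites$end[s] + flank
      p <- variants$pos[v]
      if (p >= lo && p < hi) {
        placement <- if (p >= sites$start[s] && p < sites$end[s]) {
          "in_site"
        } else "flank"
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = variants$id[v], mirna = sites$mirna[s],
          gene = sites$gene[s], site_start = sites$start[s],
          placement = placement)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(id = character(), mirna = character(),
                          gene = character(), site_start = integer(),
                          placement = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), id, mirna, site_start)
}

# --- exact test oracle: full hypergeometric enumeration -------------------

oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# random small 2x2 tables for oracle comparisons
random_tables <- function(n, max_cell = 12) {
  lapply(seq_len(n), function(i) {
    matrix(sample.int(max_cell + 1, 4, replace = TRUE) - 1L, nrow = 2)
  })
}
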