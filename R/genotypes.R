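#' Construct an unphased genotype matrix
#'
#' Genotypes are coded per sample x variant as 0 (reference homozygote),
#' 1 (heterozygote), 2 (alternate homozygote); missing calls are `NA` and
#' are never conflated with a genotype. Rows are samples, columns variants.
#'
#' @param samples Character vector of sample ids (unique).
#' @param variants Variant table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param codes Integer matrix `length(samples)` x `nrow(variants)` with
#'   entries in {0, 1, 2, NA}.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, codes) {
  variants <- validate_variants(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("Sample ids must be unique.")
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != length(samples) || ncol(codes) != nrow(variants)) {
    abort("`codes` shape must be samples x variants.")
  }
  if (!all(codes %in% c(0L, 1L, 2L, NA_integer_))) {
    abort("Genotype codes must be 0, 1, 2 or NA.")
  }
  dimnames(codes) <- list(samples, variants$id)
  structure(
    list(samples = samples, variants = variants, codes = codes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d samples x %d variants, %.1f%% missing>\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$codes))))
  print(head(x$variants, 5))
  invisible(x)
}

#' @describeIn genotype_matrix Long-format view: one row per sample x variant.
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(x$samples, times = ncol(x$codes)),
    id = rep(colnames(x$codes), each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
}

geno_column <- function(geno, variant) {
  if (is.character(variant)) {
    i <- match(variant, geno$variants$id)
    if (is.na(i)) abort(paste0("Variant not in genotype matrix: ", variant))
  } else {
    i <- as.integer(variant)
    if (i < 1 || i > ncol(geno$codes)) abort("Variant index out of range.")
  }
  i
}

#' Per-group genotype counts for one variant
#'
#' @param geno A `genotype_matrix`.
#' @param variant Variant id or column index.
#' @param sample_ids Optional subset of samples.
#' @return One-row tibble with `n_ref_hom`, `n_het`, `n_alt_hom`, `n_missing`.
#' @export
genotype_counts <- function(geno, variant, sample_ids = NULL) {
  i <- geno_column(geno, variant)
  g <- geno$codes[, i]
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, geno$samples)
    if (anyNA(keep)) abort("Unknown sample id(s) in `sample_ids`.")
    g <- g[keep]
  }
  tibble(
    n_ref_hom = sum(g == 0L, na.rm = TRUE),
    n_het = sum(g == 1L, na.rm = TRUE),
    n_alt_hom = sum(g == 2L, na.rm = TRUE),
    n_missing = sum(is.na(g))
  )
}

genotype_label <- function(code, ref, alt) {
  lab <- c(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt))
  ifelse(is.na(code), NA_character_, lab[code + 1L])
}
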