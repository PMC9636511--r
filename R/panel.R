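#' Construct a phased haplotype panel
#'
#' A panel holds the phased allele matrix from a reference haplotype resource
#' (one row per variant, two columns per individual, entries 0 = reference
#' allele, 1 = alternate allele) together with the variant table and a
#' population label per individual. It is the source of LD truth for proxy
#' expansion.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, ordered strictly increasing by (`chrom`, `pos`).
#' @param alleles Integer matrix of 0/1 with `nrow(variants)` rows and an
#'   even number of columns (two chromosomes per individual).
#' @param population Character vector, one label per individual. Recycled if
#'   length 1.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, alleles, population = "unknown") {
  variants <- validate_variants(variants)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != nrow(variants)) {
    abort("`alleles` must have one row per variant.")
  }
  if (ncol(alleles) %% 2 != 0) {
    abort("`alleles` must have an even number of columns (2 per individual).")
  }
  if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L))) {
    abort("Panel alleles must all be 0 or 1 (phased, no missing).")
  }
  n_ind <- ncol(alleles) / 2
  if (length(population) == 1) population <- rep(population, n_ind)
  if (length(population) != n_ind) {
    abort("`population` must have one label per individual.")
  }
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord, strictly = TRUE) || any(ord != seq_along(ord))) {
    variants <- variants[ord, , drop = FALSE]
    alleles <- alleles[ord, , drop = FALSE]
  }
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) {
    abort("Variant positions must be strictly increasing within chromosome.")
  }
  structure(
    list(variants = variants, alleles = alleles, population = population),
    class = "haplotype_panel"
  )
}

validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    abort(paste0("Variant table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 0)) abort("Variant positions must be >= 0 (0-based).")
  bad <- variants$id[variants$ref == variants$alt]
  if (length(bad) > 0) {
    abort(paste0("ref == alt for variant(s): ", paste(head(bad, 3), collapse = ", ")))
  }
  dup <- variants$id[duplicated(variants$id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate variant id(s): ", paste(unique(head(dup, 3)), collapse = ", ")))
  }
  variants[, req]
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel: %d variants x %d chromosomes (%d individuals)>\n",
              nrow(x$variants), ncol(x$alleles), ncol(x$alleles) / 2))
  cat("populations:", paste(names(table(x$population)), collapse = ", "), "\n")
  print(head(x$variants, 5))
  invisible(x)
}

#' @describeIn haplotype_panel Long-format view: one row per variant x
#'   chromosome with the carried allele.
#' @param x A `haplotype_panel`.
#' @param ... Unused.
#' @export
tidy.haplotype_panel <- function(x, ...) {
  tibble(
    id = rep(x$variants$id, times = ncol(x$alleles)),
    chromosome = rep(seq_len(ncol(x$alleles)), each = nrow(x$variants)),
    allele = as.integer(x$alleles)
  )
}

panel_index <- function(panel, variant) {
  if (is.character(variant)) {
    i <- match(variant, panel$variants$id)
    if (is.na(i)) abort(paste0("Variant not in panel: ", variant))
    return(i)
  }
  i <- as.integer(variant)
  if (i < 1 || i > nrow(panel$variants)) abort("Variant index out of range.")
  i
}

#' Alternate-allele frequencies of a panel
#'
#' @param panel A `haplotype_panel`.
#' @return Tibble with `id` and `alt_freq`.
#' @export
panel_alt_freqs <- function(panel) {
  tibble(id = panel$variants$id, alt_freq = rowMeans(panel$alleles))
}
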