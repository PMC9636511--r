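#' LD-proxy expansion of GWAS index variants
#'
#' For each index variant present in the panel, returns every panel variant
#' within `proxy_window_bp` on the same chromosome whose r-squared with the
#' index is at least `r2_threshold` (inclusive, matching an "LD >= 0.6"
#' rule). The index itself is always returned with `r2 = 1`. Index variants
#' absent from the panel are recorded in the `skipped` attribute rather than
#' failing the run.
#'
#' @param index_variants Character vector of index variant ids.
#' @param panel A [haplotype_panel()].
#' @param config A [pipeline_config()] supplying `r2_threshold` and
#'   `proxy_window_bp`.
#' @return Tibble with columns `index_id`, `proxy_id`, `chrom`, `pos`, `r2`,
#'   and attribute `skipped` (ids not found in the panel).
#' @export
proxy_expand <- function(index_variants, panel, config = pipeline_config()) {
  v <- panel$variants
  found <- index_variants[index_variants %in% v$id]
  skipped <- setdiff(index_variants, found)
  if (length(skipped) > 0) {
    warn(paste0("Index variant(s) absent from panel, skipped: ",
                paste(head(skipped, 5), collapse = ", ")))
  }
  rows <- purrr::map_dfr(found, function(id) {
    i <- match(id, v$id)
    cand <- which(v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= config$proxy_window_bp)
    r2 <- vapply(cand, function(j) {
      if (j == i) return(1)
      stats <- ld_from_phased(panel, i, j)
      if (isTRUE(stats$defined)) stats$r2 else NA_real_
    }, numeric(1))
    keep <- !is.na(r2) & r2 >= config$r2_threshold
    tibble(
      index_id = id, proxy_id = v$id[cand[keep]],
      chrom = v$chrom[cand[keep]], pos = v$pos[cand[keep]], r2 = r2[keep]
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble(index_id = character(), proxy_id = character(),
                   chrom = character(), pos = integer(), r2 = numeric())
  }
  rows <- arrange(rows, .data$index_id, .data$chrom, .data$pos)
  attr(rows, "skipped") <- skipped
  rows
}
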