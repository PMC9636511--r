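#' Extend a binding-site interval by flanking nucleotides
#'
#' Returns the half-open interval `[start - flank_nt, end + flank_nt)`,
#' clamped at zero. Vectorized over sites.
#'
#' @param sites Tibble of binding sites (see [read_sites()]).
#' @param flank_nt Non-negative flank width in nucleotides.
#' @return `sites` with `ext_start` and `ext_end` columns added.
#' @examples
#' extend_site(tibble::tibble(mirna = "miR-506", gene = "LAMC1", chrom = "1",
#'   start = 100L, end = 107L, strand = "-", source = "targetscan"), 25)
#' @export
extend_site <- function(sites, flank_nt = 25L) {
  if (flank_nt < 0) abort("`flank_nt` must be >= 0.")
  mutate(as_tibble(sites),
         ext_start = pmax(0L, .data$start - as.integer(flank_nt)),
         ext_end = .data$end + as.integer(flank_nt))
}

#' Intersect candidate variants with miRNA binding sites
#'
#' Emits one interaction per (variant, site) pair whose flank-extended
#' interval contains the variant position, classified as `in_site`
#' (position within the site proper, half-open) or `flank` (within the
#' ±`flank_nt` margin; the boundary at exactly `flank_nt` bp is included).
#' `distance_to_site` is 0 for in-site placements, negative upstream of the
#' site start and positive downstream of the site end. Strand is carried for
#' interpretability but does not affect the genomic intersection.
#'
#' @param variants Variant table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param sites Binding-site tibble (see [read_sites()]).
#' @param config A [pipeline_config()]; only `flank_nt` is used.
#' @return Interaction tibble sorted by (chrom, pos, gene, mirna) with
#'   columns `mirna`, `gene`, `id`, `chrom`, `pos`, `placement`,
#'   `distance_to_site`, `site_start`, `site_end`, `strand`, `source`.
#' @export
intersect_variants <- function(variants, sites, config = pipeline_config()) {
  variants <- validate_variants(variants)
  sites <- extend_site(sites, config$flank_nt)
  empty <- tibble(
    mirna = character(), gene = character(), id = character(),
    chrom = character(), pos = integer(),
    placement = character(), distance_to_site = integer(),
    site_start = integer(), site_end = integer(),
    strand = character(), source = character()
  )
  if (nrow(variants) == 0 || nrow(sites) == 0) return(empty)
  hits <- purrr::map_dfr(intersect(unique(variants$chrom), unique(sites$chrom)),
    function(ch) {
      vi <- which(variants$chrom == ch)
      si <- which(sites$chrom == ch)
      # 0-based half-open -> 1-based closed for IRanges
      q <- IRanges::IRanges(start = variants$pos[vi] + 1L, width = 1L)
      s <- IRanges::IRanges(start = sites$ext_start[si] + 1L,
                            end = sites$ext_end[si])
      ov <- IRanges::findOverlaps(q, s)
      tibble(v = vi[S4Vectors::queryHits(ov)], s = si[S4Vectors::subjectHits(ov)])
    })
  if (nrow(hits) == 0) return(empty)
  out <- tibble(
    mirna = sites$mirna[hits$s],
    gene = sites$gene[hits$s],
    id = variants$id[hits$v],
    chrom = variants$chrom[hits$v],
    pos = variants$pos[hits$v],
    site_start = sites$start[hits$s],
    site_end = sites$end[hits$s],
    strand = sites$strand[hits$s],
    source = sites$source[hits$s]
  )
  out <- mutate(
    out,
    placement = ifelse(.data$pos >= .data$site_start & .data$pos < .data$site_end,
                       "in_site", "flank"),
    distance_to_site = dplyr::case_when(
      placement == "in_site" ~ 0L,
      pos < site_start ~ pos - site_start,
      TRUE ~ pos - site_end + 1L
    )
  )
  out <- select(out, "mirna", "gene", "id", "chrom", "pos", "placement",
                "distance_to_site", "site_start", "site_end", "strand",
                "source")
  arrange(out, .data$chrom, .data$pos, .data$gene, .data$mirna,
          .data$site_start)
}

#' @importFrom dplyr select
NULL

#' Filter interactions by pathway membership
#'
#' Keeps interactions whose target gene belongs to at least one pathway
#' (restricted to inflammatory pathways when `inflammatory_only = TRUE`) and
#' annotates each kept interaction with the matching pathway names and
#' sources.
#'
#' @param interactions Interaction tibble from [intersect_variants()].
#' @param pathways Pathway membership tibble (see [read_pathways()]).
#' @param inflammatory_only Restrict to pathways flagged inflammatory.
#' @return Filtered interaction tibble with a `pathways` annotation column
#'   (semicolon-separated `pathway (source)` entries).
#' @export
filter_by_pathways <- function(interactions, pathways, inflammatory_only = TRUE) {
  if (nrow(pathways) == 0) {
    warn("Empty pathway list: all interactions removed.")
    return(mutate(interactions[0, ], pathways = character()))
  }
  if (inflammatory_only) pathways <- filter(pathways, .data$inflammatory)
  ann <- pathways |>
    mutate(label = paste0(.data$pathway, " (", .data$source, ")")) |>
    group_by(.data$gene) |>
    summarise(pathways = paste(sort(unique(.data$label)), collapse = "; "),
              .groups = "drop")
  out <- dplyr::inner_join(interactions, ann, by = "gene")
  as_tibble(out)
}

#' Per-gene interaction counts
#'
#' Counts in-site and flanking-region interactions per gene, the summary
#' used to describe a gene's miRNA targetome load (e.g. "11 target sites
#' and 16 flanking region interactions").
#'
#' @param interactions Interaction tibble.
#' @return Tibble with `gene`, `n_in_site`, `n_flank`.
#' @export
summarize_interactions <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(tibble(gene = character(), n_in_site = integer(),
                  n_flank = integer()))
  }
  interactions |>
    count(.data$gene, .data$placement) |>
    tidyr::pivot_wider(names_from = "placement", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"in_site" %in% names(d)) d$in_site <- 0L
      if (!"flank" %in% names(d)) d$flank <- 0L
      d
    })() |>
    transmute_summary()
}

transmute_summary <- function(d) {
  tibble(gene = d$gene,
         n_in_site = as.integer(d$in_site),
         n_flank = as.integer(d$flank)) |>
    arrange(gene)
}
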