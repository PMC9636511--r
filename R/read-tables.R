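#' Read miRNA binding sites from a BED-like file
#'
#' Six-or-more-column BED: chrom, start, end (0-based half-open), name,
#' score, strand, with the name field `miRNA|gene` and an optional seventh
#' column giving the evidence source (`targetscan`, `starbase`,
#' `microrna_org`, else `other`).
#'
#' @param path Path to the BED file (no header).
#' @return Tibble with columns `mirna`, `gene`, `chrom`, `start`, `end`,
#'   `strand`, `source`.
#' @export
read_sites <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(tab) < 6) abort("Site BED needs >= 6 columns.")
  name <- stringr::str_split_fixed(tab[[4]], stringr::fixed("|"), 2)
  if (any(name[, 2] == "")) {
    abort(paste0("BED name field must be 'miRNA|gene'; got '",
                 tab[[4]][name[, 2] == ""][1], "'"))
  }
  sites <- tibble(
    mirna = name[, 1],
    gene = name[, 2],
    chrom = tab[[1]],
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    strand = tab[[6]],
    source = if (ncol(tab) >= 7) tab[[7]] else "other"
  )
  known <- c("targetscan", "starbase", "microrna_org", "other")
  sites$source <- ifelse(sites$source %in% known, sites$source, "other")
  bad <- sites$start >= sites$end
  if (any(bad)) {
    abort(paste0("start >= end for site ", sites$mirna[bad][1], "|",
                 sites$gene[bad][1], " at ", sites$chrom[bad][1], ":",
                 sites$start[bad][1]))
  }
  if (!all(sites$strand %in% c("+", "-"))) {
    abort("Strand must be '+' or '-'.")
  }
  sites
}

#' Read a pathway membership table
#'
#' TSV with header and columns `pathway`, `source`, `gene`,
#' `inflammatory` (logical or 0/1). Duplicate (pathway, gene) pairs are
#' deduplicated with a warning; a pathway with no genes is an error.
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per pathway-gene membership.
#' @export
read_pathways <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("pathway", "source", "gene", "inflammatory")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Pathway TSV lacks column(s): ", paste(miss, collapse = ", ")))
  }
  tab$inflammatory <- tab$inflammatory %in% c("TRUE", "true", "1", "yes")
  if (any(is.na(tab$gene) | tab$gene == "")) {
    abort("Pathway table contains an empty gene symbol.")
  }
  dup <- duplicated(tab[, c("pathway", "gene")])
  if (any(dup)) {
    warn(paste0("Deduplicated ", sum(dup), " repeated pathway/gene pair(s)."))
    tab <- tab[!dup, , drop = FALSE]
  }
  as_tibble(tab[, req])
}

#' Read a GWAS hit list
#'
#' TSV with header and columns `variant_id`, `trait` (`risk` or `survival`),
#' `p_value`, `study`.
#'
#' @param path Path to the TSV.
#' @return Tibble of validated hits.
#' @export
read_gwas_hits <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("variant_id", "trait", "p_value", "study")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(paste0("GWAS TSV lacks column(s): ", paste(miss, collapse = ", ")))
  }
  tab$p_value <- as.numeric(tab$p_value)
  bad <- is.na(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1
  if (any(bad)) {
    abort(paste0("Invalid p-value for hit ", tab$variant_id[bad][1]))
  }
  if (!all(tab$trait %in% c("risk", "survival"))) {
    abort("GWAS trait must be 'risk' or 'survival'.")
  }
  as_tibble(tab[, req])
}

#' Read a sample phenotype/covariate table
#'
#' TSV with header; required columns `sample_id`, `status` (`case`/`control`)
#' and `bmi`; any further columns (age, sex, diabetes, family_cancer_history,
#' smoking, ...) are carried as covariates. The derived `bmi_class` column is
#' added (or validated against the cutoffs 25/30 if present).
#'
#' @param path Path to the TSV.
#' @return Tibble with `bmi_class` factor column added.
#' @export
read_samples <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  req <- c("sample_id", "status", "bmi")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(paste0("Sample TSV lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(tab$status %in% c("case", "control"))) {
    abort("Sample status must be 'case' or 'control'.")
  }
  derived <- bmi_class(tab$bmi)
  if ("bmi_class" %in% names(tab)) {
    if (!all(as.character(derived) == as.character(tab$bmi_class))) {
      bad <- which(as.character(derived) != as.character(tab$bmi_class))[1]
      abort(paste0("bmi_class inconsistent with bmi for sample ",
                   tab$sample_id[bad]))
    }
  }
  tab$bmi_class <- derived
  as_tibble(tab)
}

#' Write sites / pathways / GWAS hits in their input dialects
#'
#' @param sites,pathways,gwas Tibbles as returned by the respective readers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name write-tables
NULL

#' @rdname write-tables
#' @export
write_sites <- function(sites, path) {
  bed <- tibble(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = paste0(sites$mirna, "|", sites$gene),
    score = ".", strand = sites$strand, source = sites$source
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_pathways <- function(pathways, path) {
  readr::write_tsv(pathways, path, progress = FALSE)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_gwas_hits <- function(gwas, path) {
  readr::write_tsv(gwas, path, progress = FALSE)
  invisible(path)
}
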