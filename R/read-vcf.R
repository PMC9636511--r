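#' Read a phased haplotype panel from VCF
#'
#' Reads a VCF whose GT fields are all phased (`|` separator) and biallelic,
#' e.g. a reference-panel extract. Coordinates are converted from the VCF's
#' 1-based convention to the package's 0-based convention. The `POP` sample
#' metadata line (`##POP=<id>,...`) is not consulted; populations are taken
#' from `population` or default to `"unknown"`.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param population Optional character vector of population labels, one per
#'   sample in the VCF.
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, population = "unknown") {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    abort(paste0("Multiallelic (or ALT-less) record(s) not supported: ",
                 paste(head(fix$ID[multi], 3), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- sub(":.*", "", gt)
  bad <- matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  if (any(bad)) {
    hit <- which(bad, arr.ind = TRUE)[1, ]
    r <- hit[1]
    abort(paste0("Unphased or invalid GT '", gt[hit[1], hit[2]],
                 "' at record ", fix$ID[r], " (", fix$CHROM[r], ":", fix$POS[r],
                 "); a phased panel requires '|' separators."))
  }
  left <- substr(gt, 1, 1)
  right <- substr(gt, 3, 3)
  n_var <- nrow(gt)
  alleles <- matrix(0L, nrow = n_var, ncol = 2 * ncol(gt))
  alleles[, seq(1, 2 * ncol(gt), by = 2)] <- as.integer(left)
  alleles[, seq(2, 2 * ncol(gt), by = 2)] <- as.integer(right)
  variants <- tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT
  )
  haplotype_panel(variants, alleles, population = population)
}

#' Read unphased study genotypes
#'
#' Accepts either a VCF (any `GT` separator; `./.` missing) or the package's
#' genotype TSV dialect: one row per sample, first column `sample_id`, then
#' one column per variant whose header is `id:chrom:pos:ref:alt` (1-based
#' position) and whose cells are allele-pair strings such as `AA`, `GA`,
#' `A/G`, or `.` for missing.
#'
#' @param path Path to the file; format chosen by extension (`.vcf`/`.vcf.gz`
#'   vs anything else) unless `format` is given.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT))) abort("Multiallelic records not supported.")
  gt <- sub(":.*", "", vcfR::extract.gt(v, element = "GT"))
  codes <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  ok <- grepl("^[01][/|][01]$", gt)
  missing <- gt %in% c(".", "./.", ".|.") | is.na(gt)
  if (any(!ok & !missing)) {
    bad <- which(matrix(!ok & !missing, nrow = nrow(gt)), arr.ind = TRUE)[1, ]
    abort(paste0("Unknown genotype '", gt[bad[1], bad[2]], "' at record ",
                 fix$ID[bad[1]]))
  }
  val <- as.integer(substr(gt, 1, 1)) + as.integer(substr(gt, 3, 3))
  val[missing] <- NA_integer_
  codes[] <- t(matrix(val, nrow = nrow(gt)))
  variants <- tibble(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT
  )
  genotype_matrix(colnames(gt), variants, codes)
}

parse_variant_header <- function(h) {
  parts <- stringr::str_split(h, stringr::fixed(":"))
  bad <- lengths(parts) != 5
  if (any(bad)) {
    abort(paste0("Genotype TSV header must be id:chrom:pos:ref:alt; got '",
                 h[bad][1], "'"))
  }
  m <- do.call(rbind, parts)
  tibble(id = m[, 1], chrom = m[, 2], pos = as.integer(m[, 3]) - 1L,
         ref = m[, 4], alt = m[, 5])
}

code_allele_pair <- function(cell, ref, alt) {
  if (is.na(cell) || cell %in% c(".", "", "NA")) return(NA_integer_)
  al <- if (grepl("/", cell)) {
    strsplit(cell, "/", fixed = TRUE)[[1]]
  } else if (nchar(cell) == 2) {
    c(substr(cell, 1, 1), substr(cell, 2, 2))
  } else {
    abort(paste0("Cannot parse genotype cell '", cell, "'"))
  }
  if (length(al) != 2 || !all(al %in% c(ref, alt))) {
    abort(paste0("Unknown genotype symbol '", cell, "' for alleles ",
                 ref, "/", alt))
  }
  sum(al == alt)
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (names(tab)[1] != "sample_id") {
    abort("Genotype TSV must have 'sample_id' as its first column.")
  }
  variants <- parse_variant_header(names(tab)[-1])
  codes <- matrix(NA_integer_, nrow = nrow(tab), ncol = nrow(variants))
  for (j in seq_len(nrow(variants))) {
    codes[, j] <- vapply(tab[[j + 1]], code_allele_pair, integer(1),
                         ref = variants$ref[j], alt = variants$alt[j],
                         USE.NAMES = FALSE)
  }
  genotype_matrix(tab$sample_id, variants, codes)
}

#' Write genotypes in the package TSV dialect
#'
#' Lossless partner of [read_genotypes()]: a write-then-read round trip
#' returns an identical matrix.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  v <- geno$variants
  header <- paste(v$id, v$chrom, v$pos + 1L, v$ref, v$alt, sep = ":")
  cells <- matrix("", nrow = length(geno$samples), ncol = nrow(v))
  for (j in seq_len(nrow(v))) {
    cells[, j] <- dplyr::case_when(
      is.na(geno$codes[, j]) ~ ".",
      geno$codes[, j] == 0L ~ paste0(v$ref[j], "/", v$ref[j]),
      geno$codes[, j] == 1L ~ paste0(v$ref[j], "/", v$alt[j]),
      TRUE ~ paste0(v$alt[j], "/", v$alt[j])
    )
  }
  out <- as_tibble(as.data.frame(cells, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- header
  out <- dplyr::bind_cols(tibble(sample_id = geno$samples), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a minimal VCF
#'
#' Emits a VCF 4.2 file from a panel (phased `|` GTs) or genotype matrix
#' (unphased `/` GTs), converting positions back to 1-based. Used by the
#' simulator so synthetic fixtures exercise the real readers.
#'
#' @param x A `haplotype_panel` or `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  if (inherits(x, "haplotype_panel")) {
    n_ind <- ncol(x$alleles) / 2
    ids <- sprintf("HG%04d", seq_len(n_ind))
    gt <- matrix("", nrow = nrow(v), ncol = n_ind)
    for (k in seq_len(n_ind)) {
      gt[, k] <- paste0(x$alleles[, 2 * k - 1], "|", x$alleles[, 2 * k])
    }
  } else if (inherits(x, "genotype_matrix")) {
    ids <- x$samples
    gt <- t(ifelse(is.na(x$codes), "./.",
                   c("0/0", "0/1", "1/1")[x$codes + 1L]))
  } else {
    abort("`x` must be a haplotype_panel or genotype_matrix.")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
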