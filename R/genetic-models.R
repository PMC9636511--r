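#' Build a genetic-model 2x2 (exposure x status) table
#'
#' Collapses case and control genotype counts into the 2x2 table of one of
#' the five classical single-locus models. The reference category is listed
#' first (its odds-ratio row is 1.00 by construction):
#' * `dominant`: carriers (het + alt-hom) vs reference homozygotes;
#' * `recessive`: alt homozygotes vs the rest;
#' * `overdominant`: heterozygotes vs both homozygote classes;
#' * `codominant`: one genotype pair only, given by `pair`
#'   (reference first, e.g. `c("ref_hom", "alt_hom")`);
#' * `allelic`: allele counts (2n denominator).
#'
#' @param case,control One-row data frames of genotype counts
#'   (`n_ref_hom`, `n_het`, `n_alt_hom`).
#' @param model One of `"dominant"`, `"recessive"`, `"overdominant"`,
#'   `"codominant"`, `"allelic"`.
#' @param pair For `codominant`: length-2 character vector of genotype
#'   classes (`"ref_hom"`, `"het"`, `"alt_hom"`), reference first.
#' @return One-row tibble with `model`, `exposure`, `reference`,
#'   `case_exposed`, `case_ref`, `control_exposed`, `control_ref`,
#'   `degenerate` (TRUE when an exposure stratum is empty in both groups).
#' @examples
#' crc <- tibble::tibble(n_ref_hom = 72, n_het = 102, n_alt_hom = 31)
#' ctl <- tibble::tibble(n_ref_hom = 73, n_het = 111, n_alt_hom = 25)
#' model_table(crc, ctl, "dominant")
#' @export
model_table <- function(case, control, model, pair = NULL) {
  model <- match.arg(model, c("dominant", "recessive", "overdominant",
                              "codominant", "allelic"))
  case <- as_tibble(case)
  control <- as_tibble(control)
  grab <- function(cnt, classes) {
    sum(vapply(classes, function(cl) {
      cnt[[paste0("n_", cl)]]
    }, numeric(1)))
  }
  if (sum(case[1, c("n_ref_hom", "n_het", "n_alt_hom")]) == 0 ||
      sum(control[1, c("n_ref_hom", "n_het", "n_alt_hom")]) == 0) {
    abort("Both groups must contain genotyped samples.")
  }
  if (model == "allelic") {
    ac <- allele_counts(case)
    cc <- allele_counts(control)
    cells <- c(ac$n_alt_alleles, ac$n_ref_alleles,
               cc$n_alt_alleles, cc$n_ref_alleles)
    labels <- c("alt_allele", "ref_allele")
  } else {
    spec <- switch(model,
      dominant = list(exp = c("het", "alt_hom"), ref = "ref_hom"),
      recessive = list(exp = "alt_hom", ref = c("ref_hom", "het")),
      overdominant = list(exp = "het", ref = c("ref_hom", "alt_hom")),
      codominant = {
        if (is.null(pair) || length(pair) != 2 ||
            !all(pair %in% c("ref_hom", "het", "alt_hom"))) {
          abort("`codominant` needs `pair`, two of ref_hom/het/alt_hom.")
        }
        list(exp = pair[2], ref = pair[1])
      })
    cells <- c(grab(case, spec$exp), grab(case, spec$ref),
               grab(control, spec$exp), grab(control, spec$ref))
    labels <- c(paste(spec$exp, collapse = "+"),
                paste(spec$ref, collapse = "+"))
  }
  degenerate <- (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0
  if (degenerate) warn(paste0("Empty exposure stratum for model ", model, "."))
  tibble(
    model = if (model == "codominant") {
      paste0("codominant:", pair[1], "_vs_", pair[2])
    } else model,
    exposure = labels[1], reference = labels[2],
    case_exposed = as.integer(cells[1]), case_ref = as.integer(cells[2]),
    control_exposed = as.integer(cells[3]), control_ref = as.integer(cells[4]),
    degenerate = degenerate
  )
}

#' All genetic-model tables for one variant
#'
#' Convenience wrapper producing the dominant, recessive, overdominant,
#' three codominant pairings, and allelic tables in the conventional row
#' order.
#'
#' @inheritParams model_table
#' @return Tibble with one row per model.
#' @export
all_model_tables <- function(case, control) {
  bind_rows(
    model_table(case, control, "dominant"),
    model_table(case, control, "recessive"),
    model_table(case, control, "overdominant"),
    model_table(case, control, "codominant", pair = c("ref_hom", "alt_hom")),
    model_table(case, control, "codominant", pair = c("ref_hom", "het")),
    model_table(case, control, "codominant", pair = c("het", "alt_hom")),
    model_table(case, control, "allelic")
  )
}

#' Crude odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 exposure x status table with the Woolf
#' (log) interval `exp(ln OR +- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a
#' Wald p-value on the log scale. Any single zero cell triggers the
#' Haldane-Anscombe correction (+0.5 to every cell), flagged in the output;
#' a fully empty row or column leaves the odds ratio undefined, flagged.
#'
#' @param table Either a 2x2 matrix (rows case/control, columns
#'   exposed/reference) or a one-row tibble from [model_table()].
#' @param ci_level Confidence level, default 0.95.
#' @return One-row tibble with `or_point`, `ci_low`, `ci_high`, `p`,
#'   `adjusted = FALSE`, `n_used`, `correction`, `defined`, `note`.
#' @examples
#' crude_or(matrix(c(164, 246, 161, 257), nrow = 2, byrow = TRUE))
#' @export
crude_or <- function(table, ci_level = 0.95) {
  if (is.data.frame(table)) {
    cells <- c(table$case_exposed, table$case_ref,
               table$control_exposed, table$control_ref)
  } else {
    table <- as.matrix(table)
    stopifnot(all(dim(table) == c(2, 2)))
    cells <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  }
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("2x2 cells must be non-negative integers.")
  }
  n_used <- sum(cells)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
    return(tibble(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p = NA_real_, adjusted = FALSE, n_used = n_used,
                  correction = "none", defined = FALSE,
                  note = "empty margin: odds ratio undefined"))
  }
  correction <- "none"
  if (any(cells == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    correction <- "haldane_anscombe"
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - ci_level) / 2)
  tibble(
    or_point = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p = 2 * stats::pnorm(abs(log(or)) / se, lower.tail = FALSE),
    adjusted = FALSE, n_used = n_used, correction = correction,
    defined = TRUE,
    note = if (correction == "none") NA_character_ else
      "zero cell: Haldane-Anscombe +0.5 applied"
  )
}
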