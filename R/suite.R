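#' Default case-control and BMI contrasts
#'
#' The contrast set mirrors the usual layout of an obesity-stratified
#' case-control study: case vs control overall and within BMI strata, then
#' BMI-class contrasts pooled over status and within cases. Each contrast
#' names two groups; a group is a (status, BMI stratum) filter with
#' `status` one of `"case"`, `"control"`, `"all"` and `bmi` one of `"all"`,
#' `"normal"`, `"overweight"`, `"obese"`, `"nonobese"` (BMI < 30),
#' `"non_normal"` (BMI >= 25).
#'
#' @return Named list of contrasts usable by [run_association_suite()].
#' @export
default_contrasts <- function() {
  g <- function(status, bmi) list(status = status, bmi = bmi)
  list(
    case_vs_control_overall = list(a = g("case", "all"), b = g("control", "all")),
    case_vs_control_normal = list(a = g("case", "normal"), b = g("control", "normal")),
    case_vs_control_overweight = list(a = g("case", "overweight"), b = g("control", "overweight")),
    case_vs_control_obese = list(a = g("case", "obese"), b = g("control", "obese")),
    case_vs_control_nonobese = list(a = g("case", "nonobese"), b = g("control", "nonobese")),
    case_vs_control_non_normal = list(a = g("case", "non_normal"), b = g("control", "non_normal")),
    obese_vs_overweight = list(a = g("all", "obese"), b = g("all", "overweight")),
    obese_vs_nonobese = list(a = g("all", "obese"), b = g("all", "nonobese")),
    obese_vs_overweight_cases = list(a = g("case", "obese"), b = g("case", "overweight"))
  )
}

select_group <- function(samples, spec) {
  keep <- rep(TRUE, nrow(samples))
  if (spec$status != "all") keep <- keep & samples$status == spec$status
  cls <- as.character(samples$bmi_class)
  keep <- keep & switch(spec$bmi,
    all = TRUE,
    normal = cls == "normal",
    overweight = cls == "overweight",
    obese = cls == "obese",
    nonobese = cls != "obese",
    non_normal = cls != "normal",
    abort(paste0("Unknown BMI stratum: ", spec$bmi)))
  samples$sample_id[keep]
}

#' Hardy-Weinberg table for control strata
#'
#' HWE per variant in controls: overall and within the BMI strata
#' (>= 25, obese, < 30, overweight, normal).
#'
#' @param geno A [genotype_matrix()].
#' @param samples Sample table (see [read_samples()]).
#' @return Tibble with `id`, `stratum`, and the [hwe_test()] columns.
#' @export
hwe_controls <- function(geno, samples) {
  strata <- c(overall = "all", bmi_ge_25 = "non_normal", obese = "obese",
              nonobese = "nonobese", overweight = "overweight",
              normal = "normal")
  purrr::imap_dfr(strata, function(bmi, label) {
    ids <- select_group(samples, list(status = "control", bmi = bmi))
    ids <- intersect(ids, geno$samples)
    purrr::map_dfr(geno$variants$id, function(vid) {
      cnt <- genotype_counts(geno, vid, sample_ids = ids)
      bind_cols(tibble(id = vid, stratum = label), hwe_test(cnt))
    })
  })
}

#' Run the full case-control association suite
#'
#' For every variant x genetic model x contrast: the crude odds ratio from
#' the 2x2 model table and the covariate-adjusted odds ratio from logistic
#' regression, plus control-group Hardy-Weinberg results. Monomorphic
#' variants are reported flagged (`analyzable = FALSE`) rather than
#' dropped. Strata smaller than `config$min_stratum_size` are skipped with
#' a warning. No multiple-testing correction is applied; the number of
#' tests performed is recorded in the result.
#'
#' @param geno A [genotype_matrix()].
#' @param samples Sample table with `sample_id`, `status`, `bmi_class` and
#'   covariate columns.
#' @param contrasts Named list of contrasts, default [default_contrasts()].
#' @param config A [pipeline_config()] (covariates, CI level, minimum
#'   stratum size).
#' @return Object of class `mirtld_assoc`: list with `results` (one row per
#'   variant x model x contrast x crude/adjusted), `hwe`, `skipped`
#'   (contrast names skipped for size), `n_tests`.
#' @export
run_association_suite <- function(geno, samples,
                                  contrasts = default_contrasts(),
                                  config = pipeline_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  samples <- as_tibble(samples)
  if (!"bmi_class" %in% names(samples)) samples$bmi_class <- bmi_class(samples$bmi)
  covs <- intersect(config$covariates, names(samples))
  skipped <- character()
  results <- purrr::imap_dfr(contrasts, function(ctr, cname) {
    ids_a <- intersect(select_group(samples, ctr$a), geno$samples)
    ids_b <- intersect(select_group(samples, ctr$b), geno$samples)
    if (length(ids_a) < config$min_stratum_size ||
        length(ids_b) < config$min_stratum_size) {
      warn(paste0("Contrast '", cname, "' skipped: stratum below ",
                  config$min_stratum_size, " samples."))
      skipped <<- c(skipped, cname)
      return(tibble())
    }
    purrr::map_dfr(geno$variants$id, function(vid) {
      cnt_a <- genotype_counts(geno, vid, sample_ids = ids_a)
      cnt_b <- genotype_counts(geno, vid, sample_ids = ids_b)
      pooled <- cnt_a + cnt_b
      mono <- sum(pooled[c("n_het", "n_alt_hom")]) == 0 ||
        sum(pooled[c("n_het", "n_ref_hom")]) == 0
      if (mono) {
        return(tibble(contrast = cname, id = vid, model = "all",
                      analyzable = FALSE,
                      note = "monomorphic in this contrast; not analyzable"))
      }
      tables <- withCallingHandlers(
        all_model_tables(cnt_a, cnt_b),
        warning = function(w) invokeRestart("muffleWarning"))
      crude <- purrr::map_dfr(seq_len(nrow(tables)), function(k) {
        bind_cols(tables[k, ], crude_or(tables[k, ], ci_level = config$ci_level))
      })
      crude <- mutate(crude, covariates = "", analyzable = TRUE)
      # per-sample frame for the adjusted fits: group A coded 1
      idx <- match(c(ids_a, ids_b), geno$samples)
      dat <- tibble(
        status = rep(c(1L, 0L), c(length(ids_a), length(ids_b))),
        code = geno$codes[idx, geno_column(geno, vid)]
      )
      dat <- bind_cols(
        dat,
        samples[match(c(ids_a, ids_b), samples$sample_id), covs, drop = FALSE])
      adj_specs <- list(
        list(model = "dominant"), list(model = "recessive"),
        list(model = "overdominant"),
        list(model = "codominant", pair = c("ref_hom", "alt_hom")),
        list(model = "codominant", pair = c("ref_hom", "het")),
        list(model = "codominant", pair = c("het", "alt_hom")),
        list(model = "allelic"))
      adjusted <- purrr::map_dfr(adj_specs, function(sp) {
        adjusted_or(dat, sp$model, pair = sp$pair, covariates = covs,
                    ci_level = config$ci_level)
      })
      adjusted <- mutate(adjusted, analyzable = TRUE)
      bind_rows(crude, adjusted) |>
        mutate(contrast = cname, id = vid, .before = 1)
    })
  })
  hwe <- hwe_controls(geno, samples)
  n_tests <- if ("p" %in% names(results)) sum(!is.na(results$p)) else 0L
  structure(
    list(results = results, hwe = hwe, skipped = skipped, n_tests = n_tests,
         covariates = covs),
    class = "mirtld_assoc"
  )
}

#' @export
print.mirtld_assoc <- function(x, ...) {
  cat(sprintf("<association suite: %d result rows, %d tests, %d HWE rows>\n",
              nrow(x$results), x$n_tests, nrow(x$hwe)))
  if (length(x$skipped) > 0) {
    cat("skipped contrasts:", paste(x$skipped, collapse = ", "), "\n")
  }
  cat("adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn run_association_suite The long results table.
#' @param x A `mirtld_assoc` object.
#' @param ... Unused.
#' @export
tidy.mirtld_assoc <- function(x, ...) x$results

#' @describeIn run_association_suite One-row run summary.
#' @export
glance.mirtld_assoc <- function(x, ...) {
  tibble(n_rows = nrow(x$results), n_tests = x$n_tests,
         n_skipped_contrasts = length(x$skipped),
         n_hwe_rows = nrow(x$hwe))
}
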