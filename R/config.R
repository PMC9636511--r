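#' Pipeline configuration
#'
#' Bundles the thresholds used across the prioritization and association
#' stages. Defaults follow the conventions of GWAS proxy searches and
#' miRNA-targetome annotation: genome-wide candidate threshold `1e-6`,
#' LD proxy threshold `r2 >= 0.6` (inclusive), binding sites extended by
#' ±25 nt flanks, two-sided alpha 0.05 and 95% confidence intervals.
#'
#' @param gwas_p_threshold GWAS p-value cutoff retaining index variants.
#' @param r2_threshold Minimum r-squared (inclusive) for a proxy variant.
#' @param proxy_window_bp Maximum distance from the index variant searched
#'   for proxies, in base pairs.
#' @param flank_nt Flank added to each side of a binding site, in nucleotides.
#' @param alpha Significance level for reporting.
#' @param ci_level Confidence-interval level for odds ratios.
#' @param covariates Covariate names used by adjusted models.
#' @param min_stratum_size Strata smaller than this are skipped with a warning.
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return A list of class `mirtld_config`.
#' @examples
#' pipeline_config(r2_threshold = 0.8)
#' @export
pipeline_config <- function(gwas_p_threshold = 1e-6,
                            r2_threshold = 0.6,
                            proxy_window_bp = 1e6,
                            flank_nt = 25L,
                            alpha = 0.05,
                            ci_level = 0.95,
                            covariates = c("age", "sex", "diabetes",
                                           "family_cancer_history", "smoking"),
                            min_stratum_size = 10L,
                            rng_seed = 1L) {
  stopifnot(gwas_p_threshold > 0, gwas_p_threshold <= 1)
  if (!(r2_threshold > 0 && r2_threshold <= 1)) {
    abort("`r2_threshold` must lie in (0, 1].")
  }
  if (flank_nt < 0) abort("`flank_nt` must be >= 0.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  stopifnot(ci_level > 0, ci_level < 1, proxy_window_bp > 0)
  structure(
    list(
      gwas_p_threshold = gwas_p_threshold,
      r2_threshold = r2_threshold,
      proxy_window_bp = proxy_window_bp,
      flank_nt = as.integer(flank_nt),
      alpha = alpha,
      ci_level = ci_level,
      covariates = covariates,
      min_stratum_size = as.integer(min_stratum_size),
      rng_seed = as.integer(rng_seed)
    ),
    class = "mirtld_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `mirtld_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.mirtld_config <- function(x, ...) {
  cat("<mirtld pipeline config>\n")
  for (k in setdiff(names(x), "covariates")) {
    cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  }
  cat(sprintf("  %-18s %s\n", "covariates", paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' Classify body-mass index
#'
#' WHO cutoffs: normal `< 25`, overweight `25 <= BMI < 30`, obese `>= 30`.
#' Boundary values 25 and 30 map to overweight and obese respectively.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @examples
#' bmi_class(c(24.9, 25, 29.9, 30))
#' @export
bmi_class <- function(bmi) {
  stopifnot(is.numeric(bmi))
  if (any(!is.na(bmi) & bmi < 18.5)) {
    abort("BMI below 18.5 violates the cohort inclusion rule.")
  }
  cut(bmi, breaks = c(18.5, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}
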