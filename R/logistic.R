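#' Covariate-adjusted logistic regression for one exposure
#'
#' Fits `outcome ~ exposure + covariates` by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]) and reports
#' the exposure odds ratio `exp(beta)` with Wald confidence interval and
#' p-value. With a single binary exposure and no covariates this reproduces
#' the crude cross-product odds ratio exactly (the model is saturated).
#'
#' Complete separation (diverging coefficients / degenerate fitted
#' probabilities) is detected and flagged: the odds ratio is reported as
#' `NA` rather than a meaningless huge number. Rank-deficient designs are
#' an error naming the collinear columns.
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Name of the binary outcome column (0/1, logical, or a
#'   factor whose second level is the event).
#' @param exposure Name of the (numerically coded) exposure column.
#' @param covariates Character vector of covariate column names.
#' @param ci_level Confidence level for the Wald interval.
#' @param tol,max_iter Convergence controls passed to the IRLS fitter.
#' @return Object of class `mirtld_logit`.
#' @export
logistic_fit <- function(data, outcome, exposure, covariates = character(),
                         ci_level = 0.95, tol = 1e-10, max_iter = 100L) {
  data <- as_tibble(data)
  vars <- c(outcome, exposure, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) {
    abort(paste0("Column(s) not in data: ", paste(miss, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[vars]), vars]
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary.")
  if (length(unique(y)) < 2) abort("Outcome is constant; nothing to fit.")
  data[[outcome]] <- y
  form <- stats::as.formula(paste(
    outcome, "~", paste(c(exposure, covariates), collapse = " + ")))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  co <- summary(fit)$coefficients
  separated <- sep_warned || any(abs(co[-1, "Estimate"]) > 15)
  beta <- co[exposure, "Estimate"]
  se <- co[exposure, "Std. Error"]
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      fit = fit, exposure = exposure, covariates = covariates,
      or_point = if (separated) NA_real_ else exp(beta),
      ci_low = if (separated) NA_real_ else exp(beta - z * se),
      ci_high = if (separated) NA_real_ else exp(beta + z * se),
      p = if (separated) NA_real_ else co[exposure, "Pr(>|z|)"],
      n_used = nrow(data), converged = fit$converged,
      separated = separated,
      note = if (separated) "possible complete separation; no estimate reported"
             else NA_character_
    ),
    class = "mirtld_logit"
  )
}

#' @export
print.mirtld_logit <- function(x, ...) {
  cat(sprintf("<logistic fit: exposure '%s', n = %d>\n", x$exposure, x$n_used))
  if (x$separated) {
    cat("flagged:", x$note, "\n")
  } else {
    cat(sprintf("OR %.4f (%.4f-%.4f), p = %.3g\n",
                x$or_point, x$ci_low, x$ci_high, x$p))
  }
  if (length(x$covariates) > 0) {
    cat("adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn logistic_fit Coefficient table (log-odds scale) with Wald
#'   statistics.
#' @param x A `mirtld_logit` object.
#' @param ... Unused.
#' @export
tidy.mirtld_logit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"], statistic = co[, "z value"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @describeIn logistic_fit One-row model summary.
#' @export
glance.mirtld_logit <- function(x, ...) {
  tibble(
    or_point = x$or_point, ci_low = x$ci_low, ci_high = x$ci_high,
    p = x$p, n_used = x$n_used, log_likelihood = as.numeric(stats::logLik(x$fit)),
    converged = x$converged, separated = x$separated
  )
}

#' Adjusted association result for a genetic model
#'
#' Codes the exposure for the requested genetic model from genotype codes
#' (dominant: carrier indicator; recessive: alt-hom indicator;
#' overdominant: het indicator; codominant: indicator within the two named
#' genotype classes; allelic: additive allele dosage 0/1/2) and fits
#' [logistic_fit()] with the given covariates.
#'
#' @param data Data frame with a genotype-code column `code` (0/1/2),
#'   binary `status`, and covariate columns.
#' @param model Model name as in [model_table()].
#' @param pair Codominant genotype pair, reference first.
#' @param covariates Covariate column names.
#' @param ci_level Confidence level.
#' @return One-row tibble shaped like [crude_or()] output with
#'   `adjusted = TRUE`.
#' @export
adjusted_or <- function(data, model, pair = NULL,
                        covariates = character(), ci_level = 0.95) {
  data <- as_tibble(data)
  code <- data$code
  enc <- switch(model,
    dominant = as.integer(code >= 1),
    recessive = as.integer(code == 2),
    overdominant = as.integer(code == 1),
    allelic = as.integer(code),
    codominant = {
      idx <- c(ref_hom = 0L, het = 1L, alt_hom = 2L)[pair]
      out <- rep(NA_integer_, length(code))
      out[code == idx[1]] <- 0L
      out[code == idx[2]] <- 1L
      out
    },
    abort(paste0("Unknown model: ", model)))
  data$exposure <- enc
  model_lab <- if (model == "codominant") {
    paste0("codominant:", pair[1], "_vs_", pair[2])
  } else model
  res <- tryCatch(
    logistic_fit(data, "status", "exposure", covariates, ci_level = ci_level),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    return(tibble(model = model_lab, or_point = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p = NA_real_, adjusted = TRUE,
                  covariates = paste(covariates, collapse = ","),
                  n_used = NA_integer_, defined = FALSE,
                  note = conditionMessage(res)))
  }
  tibble(
    model = model_lab, or_point = res$or_point, ci_low = res$ci_low,
    ci_high = res$ci_high, p = res$p, adjusted = TRUE,
    covariates = paste(covariates, collapse = ","),
    n_used = res$n_used, defined = !res$separated, note = res$note
  )
}
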