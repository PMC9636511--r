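#' Simulation specification
#'
#' Describes the synthetic study: a phased reference panel with controlled
#' pairwise LD, a case-control cohort with genotype effects injected through
#' a logistic model, and a toy targetome (binding sites, pathways, GWAS
#' hits) with labeled ground truth. Defaults emulate a two-variant
#' case-control study of 215 cases and 215 controls spread over three BMI
#' classes, with covariate distributions shaped like a middle-aged clinical
#' cohort (age ~ Normal(56, 11), ~47% male).
#'
#' @param n_individuals Cohort size (cases + controls combined).
#' @param n_variants Number of panel variants.
#' @param target_ld List of `list(pair = c(i, j), r2 = x)` constraints; the
#'   second variant of each pair is built by copy-with-error from the first,
#'   so the realized r-squared concentrates on the target.
#' @param maf_range Range the per-variant minor-allele frequencies are drawn
#'   from.
#' @param case_fraction Target fraction of cases; the logistic intercept is
#'   solved to reach it in expectation.
#' @param effect_spec Tibble with columns `variant_id` (or `index`), `model`
#'   (`dominant`, `recessive`, `overdominant`, `allelic`), `or` (> 0).
#' @param covariate_coefs Named log-odds coefficients for
#'   `age` (per year, centered at 55), `sex`, `diabetes`,
#'   `family_cancer_history`, `smoking`.
#' @param bmi_fractions Probabilities of the normal/overweight/obese classes.
#' @param missing_rate Completely-at-random missingness rate of genotype
#'   calls.
#' @param n_panel_individuals Individuals in the phased panel.
#' @param rng_seed Integer seed; all generation is deterministic given it.
#' @return A list of class `mirtld_sim_spec`.
#' @export
simulation_spec <- function(n_individuals = 430,
                            n_variants = 2,
                            target_ld = list(),
                            maf_range = c(0.2, 0.5),
                            case_fraction = 0.5,
                            effect_spec = NULL,
                            covariate_coefs = c(age = 0.03, sex = 0.45,
                                                diabetes = -0.85,
                                                family_cancer_history = -0.9,
                                                smoking = -1.3),
                            bmi_fractions = c(normal = 0.27,
                                              overweight = 0.44,
                                              obese = 0.29),
                            missing_rate = 0.02,
                            n_panel_individuals = 500,
                            rng_seed = 1L) {
  stopifnot(n_individuals >= 2, n_variants >= 1,
            missing_rate >= 0, missing_rate < 1,
            case_fraction > 0, case_fraction < 1,
            length(maf_range) == 2, all(maf_range > 0), all(maf_range <= 0.5))
  for (tl in target_ld) {
    if (!is.list(tl) || !all(c("pair", "r2") %in% names(tl))) {
      abort("Each target_ld entry needs `pair` and `r2`.")
    }
    if (tl$r2 < 0 || tl$r2 > 1) {
      abort(paste0("Infeasible target r2 ", tl$r2,
                   ": must lie in [0, 1] (equal-MAF copy construction)."))
    }
  }
  if (!is.null(effect_spec)) {
    effect_spec <- as_tibble(effect_spec)
    if (any(effect_spec$or <= 0)) abort("Effect odds ratios must be > 0.")
  }
  bmi_fractions <- bmi_fractions / sum(bmi_fractions)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_variants = as.integer(n_variants), target_ld = target_ld,
         maf_range = maf_range, case_fraction = case_fraction,
         effect_spec = effect_spec, covariate_coefs = covariate_coefs,
         bmi_fractions = bmi_fractions, missing_rate = missing_rate,
         n_panel_individuals = as.integer(n_panel_individuals),
         rng_seed = as.integer(rng_seed)),
    class = "mirtld_sim_spec"
  )
}

#' Simulate a phased haplotype panel
#'
#' Draws independent Bernoulli haplotype columns at MAFs sampled from
#' `maf_range`, then rebuilds the second member of each `target_ld` pair by
#' copy-with-error from the first: each chromosome copies the parent allele
#' with probability `sqrt(r2)` and redraws from the parent's allele
#' frequency otherwise, which makes the expected allele correlation
#' `sqrt(r2)` and hence the expected r-squared equal to the target.
#'
#' @param spec A [simulation_spec()].
#' @return A [haplotype_panel()] on chromosome `"1"` with positions spread
#'   over ~1 Mb.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "mirtld_sim_spec"))
  withr_seed(spec$rng_seed, {
    n_chr <- 2L * spec$n_panel_individuals
    m <- spec$n_variants
    maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
    pos <- sort(sample.int(1e6, m))
    alleles <- matrix(rbinom(m * n_chr, 1L, rep(maf, times = n_chr)),
                      nrow = m)
    for (tl in spec$target_ld) {
      i <- tl$pair[1]; j <- tl$pair[2]
      stopifnot(i >= 1, j <= m, i != j)
      copy <- runif(n_chr) < sqrt(tl$r2)
      alleles[j, ] <- ifelse(copy, alleles[i, ],
                             rbinom(n_chr, 1L, maf[i]))
      maf[j] <- maf[i]
    }
    variants <- tibble(
      id = sprintf("rs%06d", seq_len(m)),
      chrom = "1", pos = as.integer(pos),
      ref = "A", alt = "G"
    )
    haplotype_panel(variants, alleles,
                    population = rep("synthetic", spec$n_panel_individuals))
  })
}

# run code under a temporary RNG seed, restoring state afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

model_encode <- function(code, model) {
  switch(model,
    dominant = as.numeric(code >= 1),
    recessive = as.numeric(code == 2),
    overdominant = as.numeric(code == 1),
    allelic = as.numeric(code),
    additive = as.numeric(code),
    abort(paste0("Unknown effect model: ", model)))
}

#' Simulate a case-control cohort from a panel
#'
#' Genotypes are formed by pairing two panel chromosomes per individual
#' (sampled with replacement), so the cohort inherits the panel's LD
#' structure and allele frequencies. Case status is drawn from a logistic
#' model: intercept (solved so the expected case fraction matches
#' `spec$case_fraction`) plus the model-encoded genotype effects of
#' `effect_spec` plus the covariate effects of `covariate_coefs`. BMI is
#' drawn from the class mixture and uniformly within class; genotype calls
#' are then masked completely at random at `missing_rate`.
#'
#' @param spec A [simulation_spec()].
#' @param panel A [haplotype_panel()]; defaults to `simulate_panel(spec)`.
#' @return List with `genotypes` ([genotype_matrix()]), `samples` (tibble
#'   with status, bmi, bmi_class and covariates) and `truth` (the planted
#'   parameters: per-variant effects, covariate coefficients, intercept).
#' @export
simulate_cohort <- function(spec, panel = simulate_panel(spec)) {
  stopifnot(inherits(spec, "mirtld_sim_spec"))
  withr_seed(spec$rng_seed + 1L, {
    n <- spec$n_individuals
    n_chr <- ncol(panel$alleles)
    h1 <- sample.int(n_chr, n, replace = TRUE)
    h2 <- sample.int(n_chr, n, replace = TRUE)
    codes <- t(panel$alleles[, h1, drop = FALSE] +
                 panel$alleles[, h2, drop = FALSE])
    colnames(codes) <- panel$variants$id
    covs <- tibble(
      age = round(rnorm(n, 56, 11), 1),
      sex = rbinom(n, 1, 0.47),
      diabetes = rbinom(n, 1, 0.17),
      family_cancer_history = rbinom(n, 1, 0.23),
      smoking = rbinom(n, 1, 0.09)
    )
    eta <- rep(0, n)
    if (!is.null(spec$effect_spec)) {
      for (k in seq_len(nrow(spec$effect_spec))) {
        es <- spec$effect_spec[k, ]
        j <- match(es$variant_id, panel$variants$id)
        if (is.na(j)) abort(paste0("effect_spec variant not in panel: ",
                                   es$variant_id))
        eta <- eta + log(es$or) * model_encode(codes[, j], es$model)
      }
    }
    cc <- spec$covariate_coefs
    for (nm in names(cc)) {
      x <- covs[[nm]]
      if (nm == "age") x <- x - 55
      eta <- eta + cc[[nm]] * x
    }
    f <- function(b0) mean(stats::plogis(b0 + eta)) - spec$case_fraction
    b0 <- tryCatch(uniroot(f, c(-30, 30))$root,
                   error = function(e) abort(
                     "Requested case_fraction unreachable within intercept bounds."))
    status <- rbinom(n, 1, stats::plogis(b0 + eta))
    cls <- sample(names(spec$bmi_fractions), n, replace = TRUE,
                  prob = spec$bmi_fractions)
    # upper bounds keep the 1-decimal rounding inside each class
    bmi <- round(dplyr::case_when(
      cls == "normal" ~ runif(n, 18.5, 24.9),
      cls == "overweight" ~ runif(n, 25, 29.9),
      TRUE ~ runif(n, 30, 40)
    ), 1)
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(length(codes)) < spec$missing_rate,
                     nrow = nrow(codes))
      codes[mask] <- NA_integer_
    }
    samples <- bind_cols(
      tibble(sample_id = sprintf("S%04d", seq_len(n)),
             status = ifelse(status == 1, "case", "control"),
             bmi = bmi, bmi_class = factor(cls, levels = c("normal",
                                                           "overweight",
                                                           "obese"))),
      covs)
    geno <- genotype_matrix(samples$sample_id, panel$variants, codes)
    list(
      genotypes = geno, samples = samples,
      truth = list(effect_spec = spec$effect_spec,
                   covariate_coefs = spec$covariate_coefs,
                   intercept = b0, case_fraction = mean(status))
    )
  })
}

#' Simulate a toy targetome with planted ground truth
#'
#' Builds binding sites, pathway memberships and GWAS hits around the
#' panel's variants such that every stage of the prioritization cascade has
#' known survivors: variants inside a site, at exactly the flank boundary,
#' just outside it, on genes inside vs outside inflammatory pathways, and
#' GWAS hits above vs below the p threshold.
#'
#' @param spec A [simulation_spec()].
#' @param panel A [haplotype_panel()] whose variants anchor the fixture.
#' @param config A [pipeline_config()] providing the flank width and
#'   p-value threshold being exercised.
#' @return List with `sites`, `pathways`, `gwas` tibbles and `truth`
#'   (tibble per panel variant: `in_targetome`, `inflammatory_gene`,
#'   `expected_survivor` given every variant passes the LD step).
#' @export
simulate_targetome <- function(spec, panel, config = pipeline_config()) {
  v <- panel$variants
  m <- nrow(v)
  # cycle variants through placements: in-site, flank boundary, outside
  placement <- rep(c("in_site", "flank_edge", "outside"), length.out = m)
  gene <- rep(c("LAMC1", "GNB3", "OFFPATH1"), length.out = m)
  site_w <- 7L
  sites <- purrr::map_dfr(seq_len(m), function(k) {
    p <- v$pos[k]
    start <- switch(placement[k],
      in_site = p - 3L,
      flank_edge = p + config$flank_nt,       # variant at start - flank
      outside = p + config$flank_nt + 1L)     # one bp beyond the flank
    start <- max(0L, start)
    tibble(mirna = sprintf("miR-%03d", 500 + k), gene = gene[k],
           chrom = v$chrom[k], start = start, end = start + site_w,
           strand = ifelse(k %% 2 == 0, "+", "-"),
           source = c("targetscan", "starbase", "microrna_org")[k %% 3 + 1])
  })
  pathways <- tibble(
    pathway = c("Inflammatory Response Pathway", "ERK Signaling SuperPath",
                "PI3K/Akt Signaling", "Housekeeping Pathway"),
    source = c("WikiPathways", "PathCards", "KEGG", "KEGG"),
    gene = c("LAMC1", "GNB3", "LAMC1", "OFFPATH1"),
    inflammatory = c(TRUE, TRUE, TRUE, FALSE)
  )
  gwas <- tibble(
    variant_id = v$id,
    trait = rep(c("risk", "survival"), length.out = m),
    p_value = ifelse(seq_len(m) %% 5 == 0, 1e-3,
                     config$gwas_p_threshold / 10),
    study = "synthetic GWAS"
  )
  in_targetome <- placement %in% c("in_site", "flank_edge")
  inflammatory <- gene %in% pathways$gene[pathways$inflammatory]
  passes_p <- gwas$p_value < config$gwas_p_threshold
  truth <- tibble(
    id = v$id, placement = placement, gene = gene,
    passes_gwas_p = passes_p, in_targetome = in_targetome,
    inflammatory_gene = inflammatory,
    expected_survivor = passes_p & in_targetome & inflammatory
  )
  list(sites = sites, pathways = pathways, gwas = gwas, truth = truth)
}
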