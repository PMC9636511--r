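suite_fixture <- function(seed = 404, n = 430, or = NULL) {
  eff <- if (is.null(or)) NULL else
    tibble::tibble(variant_id = "rs000001", model = "dominant", or = or)
  spec <- simulation_spec(n_individuals = n, n_variants = 2,
                          effect_spec = eff, n_panel_individuals = 300,
                          rng_seed = seed)
  simulate_cohort(spec)
}

test_that("the suite emits crude and adjusted rows per variant/model/contrast", {
  fx <- suite_fixture(or = 2)
  suite <- suppressWarnings(run_association_suite(fx$genotypes, fx$samples))
  res <- suite$results
  expect_setequal(unique(res$model),
                  c("dominant", "recessive", "overdominant", "allelic",
                    "codominant:ref_hom_vs_alt_hom",
                    "codominant:ref_hom_vs_het",
                    "codominant:het_vs_alt_hom"))
  per <- res |>
    dplyr::count(contrast, id, model) |>
    dplyr::pull(n)
  expect_true(all(per == 2)) # crude + adjusted
  adj <- dplyr::filter(res, adjusted)
  expect_true(all(adj$covariates != ""))
  expect_true(all(!is.na(res$or_point) | !is.na(res$note) | !res$defined))
  # CI brackets the point estimate wherever defined
  ok <- dplyr::filter(res, defined, !is.na(or_point))
  expect_true(all(ok$ci_low <= ok$or_point + 1e-9 &
                    ok$or_point <= ok$ci_high + 1e-9))
  expect_s3_class(autoplot(suite, contrasts = "case_vs_control_overall"),
                  "ggplot")
})

test_that("re-running the suite on identical inputs is byte-identical", {
  fx <- suite_fixture()
  s1 <- suppressWarnings(run_association_suite(fx$genotypes, fx$samples))
  s2 <- suppressWarnings(run_association_suite(fx$genotypes, fx$samples))
  expect_identical(s1$results, s2$results)
  expect_identical(s1$hwe, s2$hwe)
})

test_that("monomorphic variants yield flagged, non-crashing rows everywhere", {
  fx <- suite_fixture()
  geno <- fx$genotypes
  # plant an all-ref-homozygote variant (the all-wild-type scenario)
  codes <- cbind(geno$codes, rs_mono = 0L)
  v <- dplyr::bind_rows(geno$variants,
                        tibble::tibble(id = "rs_mono", chrom = "1",
                                       pos = max(geno$variants$pos) + 50L,
                                       ref = "T", alt = "C"))
  geno2 <- genotype_matrix(geno$samples, v, codes)
  suite <- suppressWarnings(run_association_suite(geno2, fx$samples))
  mono <- dplyr::filter(suite$results, id == "rs_mono")
  expect_true(all(!mono$analyzable))
  expect_match(mono$note[1], "monomorphic")
  hwe_mono <- dplyr::filter(suite$hwe, id == "rs_mono")
  expect_true(all(!hwe_mono$defined))
})

test_that("small strata are skipped with a warning and recorded", {
  fx <- suite_fixture(n = 60)
  # contrast against an (almost surely) tiny stratum
  contrasts <- list(
    tiny = list(a = list(status = "case", bmi = "normal"),
                b = list(status = "control", bmi = "normal")))
  cfg <- pipeline_config(min_stratum_size = 50)
  expect_warning(
    suite <- run_association_suite(fx$genotypes, fx$samples, contrasts, cfg),
    "skipped")
  expect_equal(suite$skipped, "tiny")
  expect_equal(nrow(suite$results), 0)
})

test_that("HWE control strata cover overall plus the five BMI groups", {
  fx <- suite_fixture()
  hwe <- hwe_controls(fx$genotypes, fx$samples)
  expect_setequal(unique(hwe$stratum),
                  c("overall", "bmi_ge_25", "obese", "nonobese",
                    "overweight", "normal"))
  expect_equal(nrow(hwe), 6 * 2)
})
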