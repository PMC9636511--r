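test_that("panels are deterministic under a fixed seed", {
  spec <- simulation_spec(n_variants = 5, n_panel_individuals = 100,
                          rng_seed = 12)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$variants, p2$variants)
  c1 <- simulate_cohort(spec, p1)
  c2 <- simulate_cohort(spec, p1)
  expect_identical(c1$genotypes$codes, c2$genotypes$codes)
  expect_identical(c1$samples, c2$samples)
})

test_that("target r2 of 1 duplicates the parent column exactly in law", {
  spec <- simulation_spec(n_variants = 2,
                          target_ld = list(list(pair = c(1, 2), r2 = 1)),
                          n_panel_individuals = 200, rng_seed = 2)
  panel <- simulate_panel(spec)
  expect_identical(panel$alleles[1, ], panel$alleles[2, ])
  expect_equal(ld_from_phased(panel, 1, 2)$r2, 1)
})

test_that("realized r2 and MAFs concentrate on their targets", {
  spec <- simulation_spec(
    n_variants = 3, target_ld = list(list(pair = c(1, 2), r2 = 0.36)),
    maf_range = c(0.5, 0.5), n_panel_individuals = 5000, rng_seed = 8)
  panel <- simulate_panel(spec)
  expect_lt(abs(ld_from_phased(panel, 1, 2)$r2 - 0.36), 0.03)
  freqs <- panel_alt_freqs(panel)$alt_freq
  expect_true(all(abs(freqs - 0.5) < 0.03))
})

test_that("infeasible LD targets and bad specs are rejected", {
  expect_error(simulation_spec(target_ld = list(list(pair = c(1, 2), r2 = 1.2))),
               "Infeasible")
  expect_error(simulation_spec(target_ld = list(list(pair = c(1, 2)))),
               "r2")
  expect_error(simulation_spec(effect_spec = tibble::tibble(
    variant_id = "v", model = "dominant", or = -1)), "> 0")
})

test_that("null effects give uniform association p-values across replicates", {
  spec0 <- simulation_spec(n_individuals = 300, n_variants = 1,
                           covariate_coefs = c(age = 0), missing_rate = 0,
                           n_panel_individuals = 200, rng_seed = 1)
  panel <- simulate_panel(spec0)
  ps <- vapply(1:120, function(i) {
    sp <- spec0
    sp$rng_seed <- 1000L + i
    coh <- simulate_cohort(sp, panel)
    cnt <- genotype_counts(coh$genotypes, 1,
      sample_ids = coh$samples$sample_id[coh$samples$status == "case"])
    cnt2 <- genotype_counts(coh$genotypes, 1,
      sample_ids = coh$samples$sample_id[coh$samples$status == "control"])
    crude_or(model_table(cnt, cnt2, "allelic"))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a planted dominant OR of 2 is recovered at large n", {
  spec <- simulation_spec(
    n_individuals = 20000, n_variants = 1,
    effect_spec = tibble::tibble(variant_id = "rs000001",
                                 model = "dominant", or = 2),
    covariate_coefs = c(age = 0), missing_rate = 0,
    n_panel_individuals = 2000, rng_seed = 99)
  coh <- simulate_cohort(spec)
  cases <- coh$samples$sample_id[coh$samples$status == "case"]
  ctls <- coh$samples$sample_id[coh$samples$status == "control"]
  tab <- model_table(genotype_counts(coh$genotypes, 1, cases),
                     genotype_counts(coh$genotypes, 1, ctls), "dominant")
  or <- crude_or(tab)$or_point
  expect_gte(or, 1.85)
  expect_lte(or, 2.15)
})

test_that("missing_rate 0 yields a complete matrix; rates are respected", {
  spec <- simulation_spec(n_individuals = 500, missing_rate = 0,
                          n_panel_individuals = 100, rng_seed = 3)
  coh <- simulate_cohort(spec)
  expect_false(anyNA(coh$genotypes$codes))
  spec2 <- simulation_spec(n_individuals = 2000, missing_rate = 0.1,
                           n_panel_individuals = 100, rng_seed = 3)
  coh2 <- simulate_cohort(spec2)
  expect_lt(abs(mean(is.na(coh2$genotypes$codes)) - 0.1), 0.02)
})

test_that("the cohort case fraction lands near its target", {
  spec <- simulation_spec(n_individuals = 4000, case_fraction = 0.5,
                          n_panel_individuals = 200, rng_seed = 77)
  coh <- simulate_cohort(spec)
  expect_lt(abs(mean(coh$samples$status == "case") - 0.5), 0.05)
})
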