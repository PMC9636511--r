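crc_7473 <- tibble::tibble(n_ref_hom = 72, n_het = 102, n_alt_hom = 31)
ctl_7473 <- tibble::tibble(n_ref_hom = 73, n_het = 111, n_alt_hom = 25)
crc_1547 <- tibble::tibble(n_ref_hom = 74, n_het = 98, n_alt_hom = 34)
ctl_1547 <- tibble::tibble(n_ref_hom = 61, n_het = 110, n_alt_hom = 28)

test_that("HWE chi-square has no continuity correction and exact HW gives p = 1", {
  res <- hwe_test(tibble::tibble(n_ref_hom = 25, n_het = 50, n_alt_hom = 25))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  # expected counts always sum to the observed total
  r2 <- hwe_test(ctl_7473)
  expect_equal(r2$expected_ref_hom + r2$expected_het + r2$expected_alt_hom,
               r2$n, tolerance = 1e-9)
})

test_that("HWE is invariant under swapping the homozygote classes", {
  set.seed(10)
  for (i in 1:20) {
    cnt <- tibble::tibble(n_ref_hom = sample(1:80, 1), n_het = sample(1:80, 1),
                          n_alt_hom = sample(1:80, 1))
    sw <- tibble::tibble(n_ref_hom = cnt$n_alt_hom, n_het = cnt$n_het,
                         n_alt_hom = cnt$n_ref_hom)
    expect_equal(hwe_test(cnt)$chi2, hwe_test(sw)$chi2, tolerance = 1e-12)
  }
})

test_that("HWE on a monomorphic variant is flagged, not an error", {
  res <- hwe_test(tibble::tibble(n_ref_hom = 200, n_het = 0, n_alt_hom = 0))
  expect_false(res$defined)
  expect_equal(res$note, "monomorphic")
  expect_true(is.na(res$p))
})

test_that("allele counts derive from genotype counts, degenerate included", {
  expect_equal(unlist(allele_counts(crc_7473)),
               c(n_ref_alleles = 246, n_alt_alleles = 164))
  expect_equal(unlist(allele_counts(crc_1547)),
               c(n_ref_alleles = 246, n_alt_alleles = 166))
  expect_equal(unlist(allele_counts(
    tibble::tibble(n_ref_hom = 0, n_het = 0, n_alt_hom = 7))),
    c(n_ref_alleles = 0, n_alt_alleles = 14))
})

test_that("model tables reproduce published cell layouts", {
  dom <- model_table(crc_7473, ctl_7473, "dominant")
  expect_equal(c(dom$case_exposed, dom$case_ref,
                 dom$control_exposed, dom$control_ref),
               c(133L, 72L, 136L, 73L))
  ov <- model_table(crc_1547, ctl_1547, "overdominant")
  expect_equal(c(ov$case_exposed, ov$case_ref,
                 ov$control_exposed, ov$control_ref),
               c(98L, 108L, 110L, 89L))
  # cell sums equal group totals for every model but allelic (2n there)
  tabs <- all_model_tables(crc_7473, ctl_7473)
  n_case <- sum(crc_7473); n_ctl <- sum(ctl_7473)
  full <- tabs$model %in% c("dominant", "recessive", "overdominant")
  expect_true(all(tabs$case_exposed[full] + tabs$case_ref[full] == n_case))
  expect_true(all(tabs$control_exposed[full] + tabs$control_ref[full] == n_ctl))
  al <- tabs[tabs$model == "allelic", ]
  expect_equal(al$case_exposed + al$case_ref, 2L * n_case)
  # identical groups give symmetric rows
  sym <- all_model_tables(crc_7473, crc_7473)
  expect_equal(sym$case_exposed, sym$control_exposed)
})

test_that("crude OR is the cross-product with Woolf interval", {
  or <- crude_or(matrix(c(164, 246, 161, 257), nrow = 2, byrow = TRUE))
  expect_equal(or$or_point, (164 * 257) / (246 * 161), tolerance = 1e-12)
  expect_lt(or$ci_low, or$or_point)
  expect_gt(or$ci_high, or$or_point)
  flat <- crude_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$or_point, 1)
})

test_that("zero cells trigger Haldane-Anscombe; empty margins are undefined", {
  h <- crude_or(matrix(c(0, 202, 6, 190), nrow = 2, byrow = TRUE))
  expect_equal(h$correction, "haldane_anscombe")
  expect_equal(h$or_point, (0.5 * 190.5) / (202.5 * 6.5), tolerance = 1e-12)
  und <- crude_or(matrix(c(0, 20, 0, 30), nrow = 2, byrow = TRUE))
  expect_false(und$defined)
  expect_true(is.na(und$or_point))
})

test_that("inverting the exposure coding inverts the OR and swaps the CI", {
  tab <- matrix(c(30, 70, 45, 55), nrow = 2, byrow = TRUE)
  a <- crude_or(tab)
  b <- crude_or(tab[, 2:1])
  expect_equal(b$or_point, 1 / a$or_point, tolerance = 1e-12)
  expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-12)
  expect_equal(b$ci_high, 1 / a$ci_low, tolerance = 1e-12)
})
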