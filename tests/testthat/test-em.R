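test_that("EM reduces to direct gamete counting without double heterozygotes", {
  # codes chosen so no sample is het at both loci
  codes <- cbind(c(0, 0, 1, 2, 2, 1, 0, 2),
                 c(0, 1, 0, 2, 1, 2, 2, 0))
  geno <- geno_from_codes(codes)
  fit <- em_two_locus(geno, 1, 2)
  expect_equal(fit$n_double_het, 0)
  # direct counts: each unambiguous sample contributes known haplotypes
  cnt <- geno_joint_counts(geno)
  direct <- c(
    f11 = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    f10 = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    f01 = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    f00 = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  ) / (2 * nrow(codes))
  expect_equal(fit$hap_freqs, direct, tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("EM matches the grid likelihood maximizer on mixed 20-sample data", {
  set.seed(301)
  for (rep in 1:4) {
    codes <- cbind(sample(0:2, 20, replace = TRUE, prob = c(.4, .4, .2)),
                   sample(0:2, 20, replace = TRUE, prob = c(.3, .5, .2)))
    geno <- geno_from_codes(codes)
    fit <- em_two_locus(geno, 1, 2)
    grid <- oracle_em_grid(geno_joint_counts(geno))
    expect_lt(max(abs(fit$hap_freqs - grid)), 2e-3)
  }
})

test_that("EM log-likelihood is monotone non-decreasing along the trace", {
  set.seed(99)
  codes <- cbind(sample(0:2, 50, replace = TRUE),
                 sample(0:2, 50, replace = TRUE))
  fit <- em_two_locus(geno_from_codes(codes), 1, 2)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_true(fit$converged)
})

test_that("EM agrees with phased counting when collapsing an unambiguous panel", {
  # haplotype classes with f10 = 0: double hets cannot arise in repulsion
  set.seed(17)
  f <- c(f11 = 0.3, f10 = 0, f01 = 0.2, f00 = 0.5)
  haps <- sample(1:4, 2 * 400, replace = TRUE, prob = f)
  hap_alleles <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  g1 <- hap_alleles[1, haps[1:400]] + hap_alleles[1, haps[401:800]]
  g2 <- hap_alleles[2, haps[1:400]] + hap_alleles[2, haps[401:800]]
  geno <- geno_from_codes(cbind(g1, g2))
  fit <- em_two_locus(geno, 1, 2)
  # direct phased counts of the same gametes
  direct <- tabulate(haps, 4) / 800
  # double hets here are all in coupling phase; EM should resolve them
  expect_lt(max(abs(fit$hap_freqs - direct)), 0.02)
})

test_that("no informative samples is an error; non-convergence is flagged", {
  geno <- geno_from_codes(cbind(c(NA, NA), c(0, 1)))
  expect_error(em_two_locus(geno, 1, 2), "No samples")
  set.seed(3)
  codes <- cbind(sample(0:2, 100, replace = TRUE),
                 sample(0:2, 100, replace = TRUE))
  fit <- em_two_locus(geno_from_codes(codes), 1, 2, tol = 1e-16, max_iter = 2L)
  expect_false(fit$converged)
})

test_that("symmetric double-het likelihood stays at its fixed point, noted", {
  # only double heterozygotes: coupling and repulsion phases tie exactly
  geno <- geno_from_codes(cbind(rep(1L, 10), rep(1L, 10)))
  fit <- em_two_locus(geno, 1, 2)
  expect_equal(fit$note, "symmetric likelihood")
  expect_equal(unname(fit$hap_freqs), rep(0.25, 4))
  expect_true(fit$converged)
})

test_that("unphased LD estimates recover the panel r2 at n = 500", {
  spec <- simulation_spec(
    n_individuals = 500, n_variants = 2,
    target_ld = list(list(pair = c(1, 2), r2 = 0.81)),
    missing_rate = 0, n_panel_individuals = 2000, rng_seed = 31)
  panel <- simulate_panel(spec)
  cohort <- simulate_cohort(spec, panel)
  est <- ld_from_unphased(cohort$genotypes, 1, 2)
  expect_true(est$converged)
  expect_lt(abs(est$r2 - 0.81), 0.08)
})

test_that("estimated D' is near 1 at large n when one haplotype is absent", {
  set.seed(53)
  f <- c(0.35, 0, 0.25, 0.40) # f10 = 0 -> true |D'| = 1
  n <- 10000
  haps <- matrix(sample(1:4, 2 * n, replace = TRUE, prob = f), ncol = 2)
  hap_alleles <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  geno <- geno_from_codes(cbind(
    hap_alleles[1, haps[, 1]] + hap_alleles[1, haps[, 2]],
    hap_alleles[2, haps[, 1]] + hap_alleles[2, haps[, 2]]))
  est <- ld_from_unphased(geno, 1, 2)
  expect_gte(abs(est$d_prime), 0.95)
})

test_that("tidy and glance expose the EM fit", {
  set.seed(5)
  codes <- cbind(sample(0:2, 30, replace = TRUE),
                 sample(0:2, 30, replace = TRUE))
  fit <- em_two_locus(geno_from_codes(codes), 1, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$frequency), 1, tolerance = 1e-9)
  expect_true(glance(fit)$converged)
})
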