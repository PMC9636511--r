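test_that("logistic fit with a lone binary exposure equals the crude OR", {
  set.seed(21)
  dat <- tibble::tibble(
    status = rep(c(1, 0), c(120, 150)),
    exposure = c(rbinom(120, 1, 0.55), rbinom(150, 1, 0.4)))
  fit <- logistic_fit(dat, "status", "exposure")
  a <- sum(dat$status == 1 & dat$exposure == 1)
  b <- sum(dat$status == 1 & dat$exposure == 0)
  c_ <- sum(dat$status == 0 & dat$exposure == 1)
  d <- sum(dat$status == 0 & dat$exposure == 0)
  expect_equal(fit$or_point, (a * d) / (b * c_), tolerance = 1e-6)
  expect_equal(nrow(tidy(fit)), 2)
  expect_false(glance(fit)$separated)
})

test_that("simulation recovery: beta-hat near ln(1.5) at n = 5000", {
  set.seed(77)
  n <- 5000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + log(1.5) * x))
  fit <- logistic_fit(tibble::tibble(status = y, exposure = x),
                      "status", "exposure")
  expect_lt(abs(log(fit$or_point) - log(1.5)), 0.15)
})

test_that("complete separation is flagged without an estimate", {
  dat <- tibble::tibble(status = rep(c(1, 0), each = 20),
                        exposure = rep(c(1, 0), each = 20))
  fit <- logistic_fit(dat, "status", "exposure")
  expect_true(fit$separated)
  expect_true(is.na(fit$or_point))
  expect_match(fit$note, "separation")
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(4)
  dat <- tibble::tibble(status = rbinom(50, 1, 0.5),
                        exposure = rbinom(50, 1, 0.5))
  dat$copy <- dat$exposure
  expect_error(logistic_fit(dat, "status", "exposure", covariates = "copy"),
               "collinear.*copy")
})

test_that("constant outcomes and missing columns are input errors", {
  dat <- tibble::tibble(status = rep(1, 10), exposure = rbinom(10, 1, 0.5))
  expect_error(logistic_fit(dat, "status", "exposure"), "constant")
  expect_error(logistic_fit(dat, "status", "nope"), "not in data")
})

test_that("Wald test is calibrated under the null", {
  set.seed(1234)
  reps <- 300
  n <- 500
  rej <- vapply(seq_len(reps), function(i) {
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.5)
    logistic_fit(tibble::tibble(status = y, exposure = x),
                 "status", "exposure")$p < 0.05
  }, logical(1))
  band <- stats::qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})

test_that("model encodings feed the adjusted OR correctly", {
  set.seed(9)
  n <- 800
  code <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  status <- rbinom(n, 1, plogis(-0.3 + log(2) * (code >= 1)))
  dat <- tibble::tibble(status = status, code = code,
                        age = rnorm(n, 55, 10))
  res <- adjusted_or(dat, "dominant", covariates = "age")
  expect_true(res$adjusted)
  expect_equal(res$covariates, "age")
  expect_lt(abs(log(res$or_point) - log(2)), 0.5)
  cod <- adjusted_or(dat, "codominant", pair = c("ref_hom", "alt_hom"))
  expect_equal(cod$model, "codominant:ref_hom_vs_alt_hom")
  expect_true(is.finite(cod$or_point))
})
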