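test_that("effect sizes follow the t-to-partial-correlation identity", {
  d <- make_focal(n = 201, seed = 51)
  d$study_id <- "s1"
  es <- effect_sizes(d)
  expect_equal(nrow(es), 3)

  # independent oracle: partial correlation via residual correlations
  for (j in 1:3) {
    others <- setdiff(paste0("x", 1:3), paste0("x", j))
    ry <- resid(lm(reformulate(others, "y"), data = d))
    rx <- resid(lm(reformulate(others, paste0("x", j)), data = d))
    expect_equal(es$r_partial[j], cor(ry, rx), tolerance = 1e-10)
  }
  expect_equal(es$z, atanh(es$r_partial))
  expect_equal(es$v, rep(1 / (201 - 2 - 3), 3))

  # closed-form spot values
  expect_equal(2 / sqrt(2^2 + 196), 0.1414, tolerance = 1e-3)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-3)
  expect_identical(atanh(0), 0)
})

test_that("raw-coefficient effect sizes carry OLS estimates and variances", {
  d <- make_focal(n = 80, seed = 52)
  d$study_id <- "s1"
  es <- effect_sizes(d, measure = "raw")
  fit <- summary(lm(y ~ x1 + x2 + x3, data = d))$coefficients
  expect_equal(es$z, unname(fit[-1, "Estimate"]))
  expect_equal(es$v, unname(fit[-1, "Std. Error"]^2))
})

test_that("random-effects meta-analysis recovers a common effect without heterogeneity", {
  records <- tibble::tibble(z = rep(0.3, 10), v = rep(1e-6, 10))
  fit <- meta_random(records, mcmc = mcmc_fast(seed = 61))
  expect_equal(fit$mu_z, 0.3, tolerance = 0.01)
  expect_lt(fit$tau2, 0.005)
})

test_that("meta-analysis runs on the minimal two-study input", {
  records <- tibble::tibble(z = c(0.1, 0.4), v = c(0.01, 0.02))
  fit <- meta_random(records, mcmc = mcmc_fast(seed = 62))
  expect_true(all(is.finite(c(fit$mu_z, fit$se_z, fit$tau2))))
  expect_error(meta_random(records[1, ], mcmc = mcmc_fast()), "at least 2")
})

test_that("posterior mean approaches the inverse-variance-weighted mean as tau -> 0", {
  set.seed(63)
  records <- tibble::tibble(z = rnorm(10, 0.3, 0.05), v = rep(0.01, 10))
  fit <- meta_random(records,
                     mcmc = mcmc_config(iterations = 6000, warmup = 1000,
                                        seed = 63),
                     tau_scale = 1e-4)
  fe <- sum(records$z / records$v) / sum(1 / records$v)
  expect_lt(abs(fit$mu_z - fe), 1e-3)
})

test_that("hierarchical estimates agree with the REML oracle on a large database", {
  skip_if_not_installed("metafor")
  set.seed(64)
  K <- 40
  v <- rep(0.005, K)
  z <- rnorm(K, 0.25, sqrt(0.1 + v[1]))
  records <- tibble::tibble(z = z, v = v)
  fit <- meta_random(records, mcmc = mcmc_fast(seed = 64))
  reml <- metafor::rma(yi = z, vi = v, method = "REML")
  expect_equal(fit$mu_z, as.numeric(reml$beta), tolerance = 0.03)
  expect_equal(fit$tau2, reml$tau2, tolerance = 0.05)
})

test_that("tau2 is recovered without large bias on a big database", {
  set.seed(65)
  errs <- replicate(8, {
    K <- 200
    z <- rnorm(K, 0.25, sqrt(0.1 + 0.005))
    fit <- meta_random(tibble::tibble(z = z, v = rep(0.005, K)),
                       mcmc = mcmc_fast(seed = 65))
    c(fit$mu_z - 0.25, fit$tau2 - 0.1)
  })
  expect_lt(abs(mean(errs[1, ])), 0.02)
  expect_lt(abs(mean(errs[2, ])), 0.03)
})

test_that("an uninformative moderator explains no heterogeneity", {
  set.seed(66)
  meds <- replicate(15, {
    K <- 50
    z <- rnorm(K, 0.25, sqrt(0.05 + 0.005))
    m <- rnorm(K) # independent of z
    records <- tibble::tibble(z = z, v = rep(0.005, K))
    re <- meta_random(records, mcmc = mcmc_fast(seed = 66))
    me <- meta_mixed(records, m, mcmc = mcmc_fast(seed = 67), tau2 = re$tau2)
    me$delta_tau2
  })
  expect_lt(median(meds), 0.01)
  expect_true(all(meds >= 0))
})

test_that("delta_tau2 is truncated at zero and positive when the moderator explains variance", {
  set.seed(68)
  K <- 60
  m <- rnorm(K)
  # moderator explains a large share of the between-study variance
  z <- 0.25 + sqrt(0.08) * m + rnorm(K, 0, sqrt(0.02 + 0.005))
  records <- tibble::tibble(z = z, v = rep(0.005, K))
  re <- meta_random(records, mcmc = mcmc_fast(seed = 68))
  me <- meta_mixed(records, m, mcmc = mcmc_fast(seed = 69), tau2 = re$tau2)
  expect_gt(me$delta_tau2, 0.02)
  expect_lt(me$tau2_res, re$tau2)

  # truncation branch: passing tau2 = 0 forces max(0, 0 - tau2_res) = 0
  me0 <- meta_mixed(records, m, mcmc = mcmc_fast(seed = 70), tau2 = 0)
  expect_identical(me0$delta_tau2, 0)
})

test_that("per-predictor summaries cover every predictor with moderators", {
  params <- sim_params()
  cond <- tibble::tibble(k = 5, delta_n = 0, delta_mu = 0.5, tau2 = 0.05,
                         moderator_r2 = 0.1)
  db <- simulate_database(cond, params, seed = 71)
  hs <- heterogeneity_summaries(db, mcmc = mcmc_fast(seed = 71))
  expect_equal(hs$predictor, 1:3)
  expect_true(all(hs$tau2 >= 0))
  expect_true(all(hs$delta_tau2 >= 0))
  expect_true(all(hs$tau2_res >= 0))
})
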