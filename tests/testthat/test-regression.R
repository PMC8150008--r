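make_one_predictor <- function(n = 50, beta = 0.5, seed = 90) {
  set.seed(seed)
  x <- rnorm(n)
  tibble::tibble(study_id = "focal", y = 0.5 * x + rnorm(n), x1 = x)
}

test_that("the power-weighted prior matches the conjugate closed form at known sigma", {
  d <- make_one_predictor(n = 50, seed = 91)
  pr <- prior_spec(0.4, 0.1, omega = 0.25)
  fit <- fit_swip(d, pr, mcmc = mcmc_fast(seed = 91), sigma_fixed = 1)
  # N(0.4, 0.01)^0.25 = N(0.4, 0.04); conjugate normal posterior oracle
  oracle <- conjugate_posterior(d$y, cbind(1, d$x1), mu0 = c(0, 0.4),
                                v0 = c(10, 0.04), sigma = 1)
  td <- tidy(fit)
  mcse <- td$std.error / sqrt(td$ess)
  expect_lt(abs(td$estimate[2] - oracle$mean[2]), 3 * mcse[2] + 1e-3)
  expect_equal(td$std.error[2], oracle$sd[2], tolerance = 0.05)
  expect_lt(abs(td$estimate[1] - oracle$mean[1]), 3 * mcse[1] + 1e-3)
})

test_that("raising the prior to omega equals inflating its variance by 1/omega", {
  d <- make_one_predictor(seed = 92)
  f1 <- fit_swip(d, prior_spec(0.4, 0.1, omega = 0.25),
                 mcmc = mcmc_fast(seed = 92))
  f2 <- fit_swip(d, prior_spec(0.4, 0.2, omega = 1),
                 mcmc = mcmc_fast(seed = 92))
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-12)
  expect_equal(tidy(f1)$std.error, tidy(f2)$std.error, tolerance = 1e-12)
})

test_that("a vanishing weight reduces the fit to the focal-only flat-prior limit", {
  d <- make_focal(n = 200, seed = 93)
  pr <- prior_spec(c(5, 5, 5), c(0.01, 0.01, 0.01), omega = 1e-8)
  fit <- fit_swip(d, pr, mcmc = mcmc_fast(seed = 93))
  ols <- coef(lm(y ~ x1 + x2 + x3, data = d))
  td <- tidy(fit)
  for (j in 1:3) {
    row <- td[td$term == paste0("x", j), ]
    expect_lt(abs(row$estimate - ols[j + 1]), 3 * row$std.error / sqrt(row$ess) + 0.01)
  }
})

test_that("SWIP posterior mean shrinks between the data estimate and the prior mean", {
  d <- make_one_predictor(n = 60, seed = 94)
  ols <- coef(lm(y ~ x1, data = d))[2]
  prior_mean <- 1.5 # far above the true 0.5 so the direction is unambiguous
  sds <- c()
  for (om in c(0.25, 1)) {
    fit <- fit_swip(d, prior_spec(prior_mean, 0.2, omega = om),
                    mcmc = mcmc_fast(seed = 94), sigma_fixed = 1)
    est <- tidy(fit)$estimate[2]
    expect_gt(est, min(ols, prior_mean) - 0.02)
    expect_lt(est, max(ols, prior_mean) + 0.02)
  }
})

test_that("posterior SD is non-increasing in omega on fixed data", {
  d <- make_one_predictor(n = 60, seed = 95)
  sds <- vapply(c(0.1, 0.5, 1), function(om) {
    fit <- fit_swip(d, prior_spec(0.5, 0.1, omega = om),
                    mcmc = mcmc_fast(seed = 95), sigma_fixed = 1)
    tidy(fit)$std.error[2]
  }, numeric(1))
  expect_true(all(diff(sds) < 0.005))
})

test_that("pooling with an empty database equals the focal-only fit", {
  d <- make_focal(n = 120, seed = 96)
  f1 <- fit_pooled(d, NULL, mcmc = mcmc_fast(seed = 96))
  f2 <- fit_pooled(d, d[0, ], mcmc = mcmc_fast(seed = 96))
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-12)

  # pooled fit matches the conjugate oracle at known sigma
  f3 <- fit_pooled(d, NULL, mcmc = mcmc_fast(seed = 97), sigma_fixed = 1)
  oracle <- conjugate_posterior(d$y, cbind(1, as.matrix(d[paste0("x", 1:3)])),
                                mu0 = rep(0, 4), v0 = c(10, rep(100, 3)),
                                sigma = 1)
  td <- tidy(f3)
  expect_equal(td$estimate[1:4], oracle$mean, tolerance = 0.02)
  expect_equal(td$std.error[1:4], oracle$sd, tolerance = 0.02)
})

test_that("pooling identically generated studies tightens the posterior", {
  params <- sim_params()
  focal <- simulate_focal(params, seed = 98)
  cond <- tibble::tibble(k = 5, delta_n = 0, delta_mu = 0, tau2 = 1e-8,
                         moderator_r2 = 0.1)
  db <- simulate_database(cond, sim_params(beta_f = params$beta_f,
                                           mu_beta = params$beta_f),
                          seed = 98)
  f_only <- fit_pooled(focal, NULL, mcmc = mcmc_fast(seed = 98))
  f_pool <- fit_pooled(focal, db, mcmc = mcmc_fast(seed = 98))
  expect_true(all(tidy(f_pool)$std.error[2:4] < tidy(f_only)$std.error[2:4]))
})

test_that("the robust MAP prior collapses and vague-mixes as specified", {
  d <- make_focal(n = 150, seed = 99)
  meta <- tibble::tibble(predictor = 1:3, mu_z = c(0.4, 0.0, 0.3),
                         se_z = c(0.05, 0.05, 0.05), tau2 = 0)
  # no heterogeneity, no robustification: prior is N(bridged mu, bridged se)
  fit0 <- fit_map(d, meta, mcmc = mcmc_fast(seed = 99), robust_weight = 0)
  r <- tanh(meta$mu_z)
  expect_equal(fit0$prior$mu_prior, r)
  expect_equal(fit0$prior$sd_prior, meta$se_z * (1 - r^2))

  # fully vague mixture: posterior close to the focal-only flat fit
  fit1 <- fit_map(d, meta, mcmc = mcmc_fast(seed = 100), robust_weight = 1)
  flat <- fit_pooled(d, NULL, mcmc = mcmc_fast(seed = 100))
  expect_equal(tidy(fit1)$estimate[2:4], tidy(flat)$estimate[2:4],
               tolerance = 0.02)

  # huge heterogeneity: predictive prior is vague, posterior near OLS
  meta_wide <- dplyr::mutate(meta, tau2 = 0.5)
  fit2 <- fit_map(d, meta_wide, mcmc = mcmc_fast(seed = 101))
  ols <- coef(lm(y ~ x1 + x2 + x3, data = d))
  td <- tidy(fit2)
  for (j in 1:3) {
    row <- td[td$term == paste0("x", j), ]
    expect_lt(abs(row$estimate - ols[j + 1]),
              3 * row$std.error / sqrt(row$ess) + 0.02)
  }
  expect_error(fit_map(d, meta, robust_weight = 1.5), "\\[0, 1\\]")
})

test_that("NPP endpoints reduce to the no-borrowing and full-pooling posteriors", {
  d <- make_one_predictor(n = 40, seed = 102)
  set.seed(103)
  prev <- tibble::tibble(study_id = "prev01", x1 = rnorm(60),
                         y = 0.3 * x1 + rnorm(60))
  Xf <- cbind(1, d$x1)
  v0 <- 100

  f0 <- fit_npp(d, prev, a0_grid = 0, mcmc = mcmc_fast(seed = 103))
  m_focal <- solve(crossprod(Xf) + diag(1 / v0, 2), crossprod(Xf, d$y))
  expect_equal(tidy(f0)$estimate[1:2], as.numeric(m_focal), tolerance = 1e-8)
  expect_equal(tidy(f0)$estimate[4], 0) # a0 fixed at 0

  f1 <- fit_npp(d, prev, a0_grid = 1, mcmc = mcmc_fast(seed = 104))
  Xall <- rbind(Xf, cbind(1, prev$x1))
  yall <- c(d$y, prev$y)
  m_pool <- solve(crossprod(Xall) + diag(1 / v0, 2), crossprod(Xall, yall))
  expect_equal(tidy(f1)$estimate[1:2], as.numeric(m_pool), tolerance = 1e-8)
})

test_that("the NPP mixture matches a quadrature oracle over the a0 grid", {
  d <- make_one_predictor(n = 25, seed = 105)
  set.seed(106)
  prev <- tibble::tibble(study_id = "prev01", x1 = rnorm(30),
                         y = 0.4 * x1 + rnorm(30))
  grid3 <- c(0, 0.5, 1)
  fit <- fit_npp(d, prev, a0_grid = grid3, mcmc = mcmc_fast(seed = 106))

  # oracle: per-grid NIG prior built from standard update algebra, marginal
  # likelihood of the focal data by 1-D numerical integration over sigma^2,
  # mixture of exact conditional posterior means
  Xf <- cbind(1, d$x1)
  X0 <- cbind(1, prev$x1)
  v0 <- 100; a_ig <- 0.01; b_ig <- 0.01
  V0inv <- diag(1 / v0, 2)
  w_un <- numeric(3); cond_mean <- matrix(NA_real_, 3, 2)
  for (g in 1:3) {
    a0 <- grid3[g]
    Vh_inv <- V0inv + a0 * crossprod(X0)
    Vh <- solve(Vh_inv)
    mh <- as.numeric(Vh %*% (a0 * crossprod(X0, prev$y)))
    ah <- a_ig + a0 * nrow(prev) / 2
    bh <- b_ig + (a0 * sum(prev$y^2) - sum(mh * (Vh_inv %*% mh))) / 2
    w_un[g] <- nig_marginal_quadrature(d$y, Xf, mh, Vh, ah, bh)
    Vn_inv <- Vh_inv + crossprod(Xf)
    cond_mean[g, ] <- as.numeric(solve(Vn_inv, Vh_inv %*% mh + crossprod(Xf, d$y)))
  }
  w <- w_un / sum(w_un)
  expect_equal(fit$a0_weights, w, tolerance = 1e-6)
  expect_equal(tidy(fit)$estimate[1:2], as.numeric(colSums(w * cond_mean)),
               tolerance = 1e-6)
})

test_that("fits report diagnostics, tidiers and plots", {
  d <- make_focal(n = 80, seed = 107)
  fit <- fit_pooled(d, NULL, mcmc = mcmc_fast(seed = 107))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "median", "rhat", "ess"))
  expect_true(all(is.finite(td$rhat)))
  g <- glance(fit)
  expect_equal(g$arm, "pooled")
  expect_true(is.logical(g$converged))
  expect_s3_class(autoplot(fit), "ggplot")

  expect_error(fit_swip(d, prior_spec(0, 1), mcmc = mcmc_fast()), "one row")
  d_sing <- dplyr::mutate(d, x2 = x1)
  expect_error(fit_pooled(d_sing, NULL, mcmc = mcmc_fast()), "singular")
})
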