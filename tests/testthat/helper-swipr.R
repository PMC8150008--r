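# Shared fixtures and oracles for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# Fast sampler settings for unit tests (acceptance tests use the study
# defaults from mcmc_config()).
mcmc_fast <- function(seed = 1L) {
  mcmc_config(chains = 2, iterations = 1500, warmup = 500, seed = seed)
}

# A small focal dataset built directly (independent of simulate_focal) for
# tests where the generator itself is not under test.
make_focal <- function(n = 100, beta = c(0.5, 0.25, -0.5), sigma = 1,
                       seed = 1, intercept = 0) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  y <- intercept + as.numeric(X %*% beta) + rnorm(n, sd = sigma)
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("x", seq_len(p))
  dplyr::bind_cols(tibble::tibble(study_id = "focal", y = y), d)
}

# Conjugate posterior for normal regression with KNOWN sigma and independent
# normal priors N(mu0_j, v0_j) on the coefficients (intercept included):
# an independent oracle for the MCMC fits.
conjugate_posterior <- function(y, Xd, mu0, v0, sigma = 1) {
  P <- diag(1 / v0, length(v0))
  V <- solve(crossprod(Xd) / sigma^2 + P)
  m <- V %*% (crossprod(Xd, y) / sigma^2 + P %*% mu0)
  list(mean = as.numeric(m), sd = unname(sqrt(diag(V))))
}

# Multivariate normal log-density with covariance sigma2 * S (chol-based),
# used by the NPP quadrature oracle.
dmvnorm_log <- function(y, mean, S, sigma2) {
  n <- length(y)
  R <- chol(S)
  z <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(R))) -
    sum(z^2) / (2 * sigma2)
}

# Scaled-down rerun of the simulation study used by several acceptance
# checks: the 8 grid-corner conditions, 5 replications, all four analysis
# arms, at the study MCMC settings (4 chains x 2,000 iterations, 1,000
# burn-in). Run once and cached for the session.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_study <- function() {
  if (is.null(.acceptance_cache$study)) {
    grid <- grid_corners(sim_grid())
    .acceptance_cache$study <- run_study(
      grid, sim_params(),
      arms = c("pooled", "npp", "map", "swip"),
      mcmc = mcmc_config(seed = 424242L),
      n_reps = 5
    )
  }
  .acceptance_cache$study
}

# Marginal likelihood of y under a normal-inverse-gamma prior, computed by
# 1-D numerical quadrature over log(sigma^2) on a fine fixed grid
# (independent of the package's multivariate-t closed form).
nig_marginal_quadrature <- function(y, Xd, m0, V0, a0, b0,
                                    n_grid = 200001L) {
  S <- diag(length(y)) + Xd %*% V0 %*% t(Xd)
  mu <- as.numeric(Xd %*% m0)
  g <- seq(log(1e-5), log(1e5), length.out = n_grid)
  s2 <- exp(g)
  # IG(a0, b0) density x Jacobian of the log transform
  f <- vapply(seq_along(s2), function(i) {
    exp(dmvnorm_log(y, mu, S, s2[i]) +
          a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2[i]) -
          b0 / s2[i] + g[i])
  }, numeric(1))
  sum(f) * (g[2] - g[1])
}
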