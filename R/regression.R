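#' Informative prior specification for regression coefficients
#'
#' One row per predictor: the prior mean and SD on the coefficient scale and
#' the similarity weight that the prior is raised to. A weighted normal prior
#' N(mu, sd^2)^omega is proportional to N(mu, sd^2 / omega), so smaller
#' weights flatten the prior and reduce its informativeness.
#'
#' @param mu_prior Numeric vector of prior means.
#' @param sd_prior Numeric vector of prior SDs (> 0).
#' @param omega Similarity weights in `[0, 1]` (recycled if scalar).
#' @return A tibble with columns `predictor`, `mu_prior`, `sd_prior`, `omega`.
#' @export
prior_spec <- function(mu_prior, sd_prior, omega = 1) {
  if (any(sd_prior <= 0)) stop("`sd_prior` must be positive", call. = FALSE)
  if (any(omega < 0 | omega > 1)) {
    stop("`omega` must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    predictor = seq_along(mu_prior),
    mu_prior = as.numeric(mu_prior),
    sd_prior = as.numeric(sd_prior),
    omega = rep_len(as.numeric(omega), length(mu_prior))
  )
}

#' Build the similarity-weighted prior from meta-analytic summaries
#'
#' Converts per-predictor pooled effects into coefficient-scale prior
#' hyperparameters and attaches the similarity weights. With
#' `scale = "r"` (default, for meta-analyses of Fisher-z partial
#' correlations) the pooled mean is back-transformed via tanh and its SE via
#' the delta method, SE_r = SE_z (1 - r^2); the r-scale values are then used
#' directly as coefficient-scale hyperparameters, which is adequate for
#' standardized predictors with unit error variance. With
#' `scale = "identity"` (for meta-analyses of raw coefficients, see
#' [effect_sizes()] `measure = "raw"`) the summaries are used as-is.
#'
#' @param meta Tibble from [heterogeneity_summaries()] (`predictor`, `mu_z`,
#'   `se_z` required).
#' @param weights Tibble from [similarity_weights()] (`predictor`, `omega`),
#'   or a numeric vector of weights; defaults to 1 (unweighted prior).
#' @param scale `"r"` or `"identity"`.
#' @return A [prior_spec()] tibble.
#' @export
swip_prior <- function(meta, weights = NULL, scale = c("r", "identity")) {
  scale <- match.arg(scale)
  stopifnot(all(c("predictor", "mu_z", "se_z") %in% names(meta)))
  om <- if (is.null(weights)) {
    rep(1, nrow(meta))
  } else if (is.data.frame(weights)) {
    if (!all(meta$predictor %in% weights$predictor)) {
      stop("`weights` missing some predictors", call. = FALSE)
    }
    weights$omega[match(meta$predictor, weights$predictor)]
  } else {
    rep_len(as.numeric(weights), nrow(meta))
  }
  if (scale == "r") {
    r <- tanh(meta$mu_z)
    mu <- r
    sdv <- meta$se_z * (1 - r^2)
  } else {
    mu <- meta$mu_z
    sdv <- meta$se_z
  }
  prior_spec(mu, sdv, om)[order(meta$predictor), ]
}

# ---- JAGS machinery -------------------------------------------------------

# All four analysis arms are ordinary normal linear regressions; the
# likelihood is passed to JAGS through its exact sufficient-statistic
# factorization (OLS coefficients ~ MVN(beta, sigma^2 (X'X)^-1) independent
# of RSS ~ sigma^2 * chisq(n - q)), so sampling cost does not grow with n.
# Every coefficient prior is a two-component normal mixture; pure normal
# priors put weight 1 on the first component.
jags_reg_template <- function(sigma_scale, sigma_fixed) {
  sigma_block <- if (!is.null(sigma_fixed)) {
    "prec <- pow(sigma_fixed, -2)"
  } else if (sigma_scale == "sd") {
    "sigma ~ dt(0, pow(2.5, -2), 1) T(0,)\n  prec <- pow(sigma, -2)"
  } else {
    "sig2 ~ dt(0, pow(2.5, -2), 1) T(0,)\n  prec <- 1 / sig2\n  sigma <- sqrt(sig2)"
  }
  paste0("
model {
  bhat ~ dmnorm(beta[1:q], prec * XtX)
  rss ~ dgamma(0.5 * (n - q), 0.5 * prec)
  beta[1] ~ dnorm(0, 1 / b0_var)
  for (j in 2:q) {
    comp[j] ~ dcat(pw[j - 1, 1:2])
    beta[j] ~ dnorm(pmu[j - 1, comp[j]], 1 / pvar[j - 1, comp[j]])
  }
  ", sigma_block, "
}")
}

# Fit one regression arm given per-coefficient mixture priors.
fit_bayes_lm <- function(y, X, pmu, pvar, pw, mcmc, arm,
                         b0_var = 10, sigma_scale = c("sd", "variance"),
                         sigma_fixed = NULL, prior = NULL) {
  sigma_scale <- match.arg(sigma_scale)
  Xd <- cbind(1, X)
  q <- ncol(Xd)
  n <- length(y)
  if (n <= q) stop("need more rows than coefficients", call. = FALSE)
  if (qr(Xd)$rank < q) stop("singular design matrix", call. = FALSE)
  ols <- lm.fit(Xd, y)
  dat <- list(
    bhat = as.numeric(ols$coefficients),
    rss = sum(ols$residuals^2),
    XtX = crossprod(Xd),
    n = n, q = q, b0_var = b0_var,
    pmu = pmu, pvar = pvar, pw = pw
  )
  if (!is.null(sigma_fixed)) dat$sigma_fixed <- sigma_fixed
  monitor <- c("beta", if (is.null(sigma_fixed)) "sigma")
  fit <- run_jags(jags_reg_template(sigma_scale, sigma_fixed), dat,
                  monitor, mcmc)
  sm <- fit$summary
  terms <- c("(Intercept)", paste0("x", seq_len(q - 1)),
             if (is.null(sigma_fixed)) "sigma")
  jags_names <- c(paste0("beta[", seq_len(q), "]"),
                  if (is.null(sigma_fixed)) "sigma")
  sm <- sm[match(jags_names, sm$term), ]
  sm$term <- terms
  new_swip_fit(arm = arm, summary = sm, converged = fit$converged,
               retried = fit$retried, mcmc = mcmc, n = n, p = q - 1,
               prior = prior)
}

new_swip_fit <- function(arm, summary, converged, retried, mcmc, n, p,
                         prior = NULL, extra = list()) {
  structure(
    c(list(arm = arm, summary = summary, converged = converged,
           retried = retried, mcmc = mcmc, n = n, p = p, prior = prior),
      extra),
    class = "swip_fit"
  )
}

#' @export
print.swip_fit <- function(x, ...) {
  cat(sprintf("<swip_fit> arm = %s, n = %d, p = %d%s\n", x$arm, x$n, x$p,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$summary)
  invisible(x)
}

# ---- Analysis arms --------------------------------------------------------

#' Fit the similarity-weighted informative prior (SWIP) regression
#'
#' Bayesian multiple regression y ~ N(beta0 + X beta, sigma^2) with
#' beta0 ~ N(0, variance 10), a half-Cauchy(0, 2.5) prior on the error SD,
#' and the similarity-weighted informative prior
#' N(mu_j, sd_j^2)^omega_j = N(mu_j, sd_j^2 / omega_j) on each coefficient.
#' Weights below `omega_floor` replace the prior by a diffuse
#' N(0, `diffuse_var`) to avoid an improper limit; this matches the weighted
#' prior's behavior (its informativeness vanishes as omega tends to 0).
#'
#' @param focal Focal-study tibble (`y`, `x1`..`xp`).
#' @param prior A [prior_spec()] tibble matching the predictors.
#' @param mcmc A [mcmc_config()].
#' @param omega_floor Weight below which the prior is treated as diffuse.
#' @param diffuse_var Variance of the diffuse replacement prior.
#' @param sigma_scale `"sd"` (half-Cauchy on sigma, default) or `"variance"`
#'   (the literal half-Cauchy on sigma^2).
#' @param sigma_fixed Optional known error SD; when supplied sigma is not
#'   sampled (used for conjugate closed-form checks).
#' @return A `swip_fit` object; see [tidy.swip_fit()].
#' @export
#' @examples
#' \donttest{
#' focal <- simulate_focal(sim_params(), seed = 1)
#' pr <- prior_spec(c(0.4, 0, 0.3), c(0.1, 0.1, 0.1), omega = c(.8, .8, .8))
#' fit_swip(focal, pr, mcmc_config(iterations = 400, warmup = 200))
#' }
fit_swip <- function(focal, prior, mcmc = mcmc_config(), omega_floor = 1e-3,
                     diffuse_var = 100, sigma_scale = "sd",
                     sigma_fixed = NULL) {
  X <- predictor_matrix(focal)
  p <- ncol(X)
  stopifnot(is.data.frame(prior),
            all(c("mu_prior", "sd_prior", "omega") %in% names(prior)))
  if (nrow(prior) != p) {
    stop("`prior` must have one row per predictor", call. = FALSE)
  }
  low <- prior$omega < omega_floor
  pmu <- cbind(ifelse(low, 0, prior$mu_prior), 0)
  pvar <- cbind(ifelse(low, diffuse_var, prior$sd_prior^2 / pmax(prior$omega, omega_floor)),
                diffuse_var)
  pw <- cbind(rep(1, p), rep(0, p))
  fit_bayes_lm(focal$y, X, pmu, pvar, pw, mcmc, arm = "swip",
               sigma_scale = sigma_scale, sigma_fixed = sigma_fixed,
               prior = prior)
}

#' Fit the pooled non-informative comparator
#'
#' Stacks the focal study's rows with all previous studies' rows and fits a
#' single Bayesian regression with diffuse N(0, variance 100) coefficient
#' priors (intercept N(0, 10), half-Cauchy(0, 2.5) error scale).
#'
#' @inheritParams fit_swip
#' @param db A `swip_database`, a stacked study tibble, or `NULL` for a
#'   focal-only non-informative fit.
#' @param diffuse_var Coefficient prior variance.
#' @return A `swip_fit`.
#' @export
fit_pooled <- function(focal, db = NULL, mcmc = mcmc_config(),
                       diffuse_var = 100, sigma_scale = "sd",
                       sigma_fixed = NULL) {
  studies <- if (inherits(db, "swip_database")) db$studies else db
  xcols <- predictor_cols(focal)
  dat <- if (is.null(studies) || nrow(studies) == 0L) {
    focal[c("y", xcols)]
  } else {
    dplyr::bind_rows(focal[c("y", xcols)], studies[c("y", xcols)])
  }
  p <- length(xcols)
  pmu <- cbind(rep(0, p), 0)
  pvar <- cbind(rep(diffuse_var, p), diffuse_var)
  pw <- cbind(rep(1, p), rep(0, p))
  fit_bayes_lm(dat$y, as.matrix(dat[xcols]), pmu, pvar, pw, mcmc,
               arm = "pooled", sigma_scale = sigma_scale,
               sigma_fixed = sigma_fixed)
}

#' Fit the robust meta-analytic predictive (MAP) prior comparator
#'
#' The MAP prior for each coefficient is the predictive distribution of a
#' new study's effect implied by the random-effects meta-analysis,
#' N(mu_j, se_j^2 + tau2_j) on the Fisher-z scale, bridged to the
#' coefficient scale like [swip_prior()]. It is robustified as a
#' two-component mixture with a diffuse N(0, `diffuse_var`) component of
#' weight `robust_weight`. The regression model is otherwise identical to
#' [fit_swip()].
#'
#' @inheritParams fit_swip
#' @param meta Per-predictor tibble from [heterogeneity_summaries()].
#' @param robust_weight Mixture weight of the diffuse component in `[0, 1]`.
#' @param scale Scale bridge passed to the hyperparameters (see
#'   [swip_prior()]).
#' @return A `swip_fit`.
#' @export
fit_map <- function(focal, meta, mcmc = mcmc_config(), robust_weight = 0.2,
                    diffuse_var = 100, scale = c("r", "identity"),
                    sigma_scale = "sd", sigma_fixed = NULL) {
  scale <- match.arg(scale)
  X <- predictor_matrix(focal)
  p <- ncol(X)
  stopifnot(all(c("predictor", "mu_z", "se_z", "tau2") %in% names(meta)))
  if (nrow(meta) != p) {
    stop("`meta` must have one row per predictor", call. = FALSE)
  }
  if (robust_weight < 0 || robust_weight > 1) {
    stop("`robust_weight` must lie in [0, 1]", call. = FALSE)
  }
  meta <- meta[order(meta$predictor), ]
  pred_sd_z <- sqrt(meta$se_z^2 + meta$tau2)
  if (scale == "r") {
    r <- tanh(meta$mu_z)
    mu <- r
    sdv <- pred_sd_z * (1 - r^2)
  } else {
    mu <- meta$mu_z
    sdv <- pred_sd_z
  }
  pmu <- cbind(mu, 0)
  pvar <- cbind(sdv^2, diffuse_var)
  pw <- cbind(1 - robust_weight, rep(robust_weight, p))
  fit_bayes_lm(focal$y, X, pmu, pvar, pw, mcmc, arm = "map",
               sigma_scale = sigma_scale, sigma_fixed = sigma_fixed,
               prior = tibble::tibble(predictor = meta$predictor,
                                      mu_prior = mu, sd_prior = sdv,
                                      robust_weight = robust_weight))
}

# ---- Normalized power prior (conjugate closed forms) ----------------------

# One normal-inverse-gamma update with likelihood weight w:
# beta | sigma2 ~ N(m, sigma2 V), sigma2 ~ IG(a, b).
nig_update <- function(m, V, a, b, X, y, w = 1) {
  Vinv <- solve(V)
  Vn_inv <- Vinv + w * crossprod(X)
  Vn <- solve(Vn_inv)
  mn <- as.numeric(Vn %*% (Vinv %*% m + w * crossprod(X, y)))
  an <- a + w * length(y) / 2
  bn <- b + (w * sum(y^2) + sum(m * (Vinv %*% m)) -
               sum(mn * (Vn_inv %*% mn))) / 2
  list(m = mn, V = Vn, a = an, b = bn)
}

# Log marginal likelihood of y under a NIG prior (multivariate-t closed form).
nig_log_marginal <- function(prior, post, n) {
  -n / 2 * log(2 * pi) +
    0.5 * (determinant(post$V)$modulus - determinant(prior$V)$modulus) +
    prior$a * log(prior$b) - post$a * log(post$b) +
    lgamma(post$a) - lgamma(prior$a)
}

#' Fit the normalized power prior (NPP) comparator
#'
#' Normal-inverse-gamma power prior with a random borrowing weight a0 given
#' a uniform prior discretized on `a0_grid`. For each grid value the
#' a0-weighted historical likelihood (all previous studies stacked) updates
#' the diffuse NIG baseline in closed form; the normalizing constant and the
#' focal-data marginal likelihood are the conjugate multivariate-t forms, so
#' the posterior over a0 and the final mixture posterior are exact — no MCMC
#' is needed. Posterior means and SDs are analytic mixture moments;
#' Gelman-Rubin and ESS diagnostics for the regression parameters are
#' computed from chains of exact independent draws to honor the same
#' convergence contract as the sampled arms. `a0` itself is enumerated
#' exactly on the grid, so no chain diagnostic applies to it (its `rhat`
#' and `ess` are `NA`).
#'
#' @inheritParams fit_pooled
#' @param a0_grid Grid of borrowing weights in `[0, 1]` (default 21 equally
#'   spaced points).
#' @param v0 Baseline prior coefficient variance (times sigma^2).
#' @param ig_a,ig_b Baseline inverse-gamma shape and scale for sigma^2.
#' @return A `swip_fit` with extra fields `a0_grid`, `a0_weights` and the
#'   per-grid conditional posteriors in `npp_detail`.
#' @export
fit_npp <- function(focal, db, a0_grid = seq(0, 1, length.out = 21),
                    mcmc = mcmc_config(), v0 = 100, ig_a = 0.01,
                    ig_b = 0.01) {
  studies <- if (inherits(db, "swip_database")) db$studies else db
  xcols <- predictor_cols(focal)
  q <- length(xcols) + 1L
  Xf <- cbind(1, as.matrix(focal[xcols]))
  if (qr(Xf)$rank < q) stop("singular design matrix", call. = FALSE)
  yf <- focal$y
  X0 <- if (is.null(studies) || nrow(studies) == 0L) {
    matrix(0, 0, q)
  } else {
    cbind(1, as.matrix(studies[xcols]))
  }
  y0 <- if (nrow(X0)) studies$y else numeric(0)
  base <- list(m = rep(0, q), V = diag(v0, q), a = ig_a, b = ig_b)

  per <- lapply(a0_grid, function(a0) {
    pr <- if (a0 > 0 && nrow(X0)) {
      nig_update(base$m, base$V, base$a, base$b, X0, y0, w = a0)
    } else {
      base
    }
    po <- nig_update(pr$m, pr$V, pr$a, pr$b, Xf, yf, w = 1)
    list(prior = pr, post = po,
         logml = as.numeric(nig_log_marginal(pr, po, length(yf))))
  })
  logml <- vapply(per, `[[`, numeric(1), "logml")
  w <- exp(logml - max(logml))
  w <- w / sum(w)

  # analytic mixture moments (coefficients: multivariate-t marginals)
  mom <- mixture_moments(per, w, q)
  draws <- npp_exact_draws(per, w, q, mcmc, a0_grid)
  sm_draws <- summarize_chains(draws)
  terms <- c("(Intercept)", paste0("x", seq_len(q - 1)), "sigma", "a0")
  sm <- tibble::tibble(
    term = terms,
    estimate = c(mom$beta_mean, mom$sigma_mean, sum(w * a0_grid)),
    std.error = c(mom$beta_sd, mom$sigma_sd,
                  sqrt(max(0, sum(w * a0_grid^2) - sum(w * a0_grid)^2))),
    median = sm_draws$median[match(terms, sm_draws$term)],
    rhat = sm_draws$rhat[match(terms, sm_draws$term)],
    ess = sm_draws$ess[match(terms, sm_draws$term)]
  )
  # a0's posterior is enumerated exactly on the grid, not sampled; a
  # chain-based convergence diagnostic does not apply to it (and is unstable
  # when nearly all mass sits on one grid point)
  sm$rhat[sm$term == "a0"] <- NA_real_
  sm$ess[sm$term == "a0"] <- NA_real_
  new_swip_fit(
    arm = "npp", summary = sm,
    converged = !any(sm$rhat > mcmc$rhat_threshold, na.rm = TRUE),
    retried = FALSE, mcmc = mcmc, n = length(yf), p = q - 1L,
    extra = list(a0_grid = a0_grid, a0_weights = w, npp_detail = per)
  )
}

mixture_moments <- function(per, w, q) {
  bm <- matrix(0, length(per), q)
  bv <- matrix(0, length(per), q)
  sm <- numeric(length(per))
  s2 <- numeric(length(per))
  for (g in seq_along(per)) {
    po <- per[[g]]$post
    bm[g, ] <- po$m
    bv[g, ] <- diag(po$V) * po$b / (po$a - 1)        # t marginal variance
    s2[g] <- po$b / (po$a - 1)                       # E[sigma^2]
    sm[g] <- sqrt(po$b) * exp(lgamma(po$a - 0.5) - lgamma(po$a)) # E[sigma]
  }
  beta_mean <- colSums(w * bm)
  beta_sd <- sqrt(pmax(0, colSums(w * (bv + bm^2)) - beta_mean^2))
  sigma_mean <- sum(w * sm)
  sigma_sd <- sqrt(max(0, sum(w * s2) - sigma_mean^2))
  list(beta_mean = beta_mean, beta_sd = beta_sd,
       sigma_mean = sigma_mean, sigma_sd = sigma_sd)
}

# Exact independent draws from the NPP mixture posterior, organized as
# chains so the usual convergence diagnostics apply.
npp_exact_draws <- function(per, w, q, mcmc, a0_grid) {
  iter <- mcmc$iterations - mcmc$warmup
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(derive_seed(mcmc$seed, 5000L + ch))
    g <- sample.int(length(per), iter, replace = TRUE, prob = w)
    out <- matrix(NA_real_, iter, q + 2)
    for (i in seq_len(iter)) {
      po <- per[[g[i]]]$post
      sig2 <- 1 / rgamma(1, po$a, rate = po$b)
      beta <- po$m + sqrt(sig2) * as.numeric(t(chol(po$V)) %*% rnorm(q))
      out[i, ] <- c(beta, sqrt(sig2), a0_grid[g[i]])
    }
    colnames(out) <- c("(Intercept)", paste0("x", seq_len(q - 1)),
                       "sigma", "a0")
    coda::mcmc(out, start = 1)
  })
  coda::mcmc.list(chains)
}
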