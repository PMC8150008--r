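#' Per-study Fisher-z partial-correlation effect sizes
#'
#' For every study in the database and every predictor, fits the study's
#' ordinary least-squares regression and converts the predictor's
#' t-statistic into a partial correlation r = t / sqrt(t^2 + df) with
#' df = n - p - 1, then applies Fisher's r-to-z transformation z = atanh(r).
#' The known sampling variance is v = 1 / (n - q - 3) with q = p - 1
#' covariates partialled out. Partial correlations numerically at +-1 are
#' clamped to +-(1 - 1e-8) with a warning.
#'
#' @param db A `swip_database` or a stacked tibble of studies with a
#'   `study_id` column and columns `y`, `x1`..`xp`.
#' @param measure `"zcor"` (Fisher-z partial correlations, default) or
#'   `"raw"` (raw OLS coefficients with their squared standard errors as
#'   sampling variances, for the alternative raw-coefficient meta-analysis
#'   mode).
#' @return A tibble with one row per study x predictor: `study_id`,
#'   `predictor`, `n`, `r_partial` (`NA` for `measure = "raw"`), `z` (the
#'   effect on the chosen scale), `v`.
#' @export
#' @examples
#' cond <- sim_grid(levels_k = 3, levels_dn = 0, levels_dmu = 0.5,
#'                  levels_tau2 = 0.05)[1, ]
#' db <- simulate_database(cond, sim_params(), seed = 3)
#' effect_sizes(db)
effect_sizes <- function(db, measure = c("zcor", "raw")) {
  measure <- match.arg(measure)
  studies <- if (inherits(db, "swip_database")) db$studies else db
  stopifnot("study_id" %in% names(studies))
  xcols <- predictor_cols(studies)
  p <- length(xcols)
  studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::group_map(function(d, key) {
      n <- nrow(d)
      if (n <= p + 4) {
        stop("study ", key$study_id, " has too few rows (n must exceed p + 4)",
             call. = FALSE)
      }
      fit <- lm(y ~ ., data = d[c("y", xcols)])
      cf <- summary(fit)$coefficients[xcols, , drop = FALSE]
      if (measure == "raw") {
        return(tibble::tibble(
          study_id = key$study_id, predictor = seq_len(p), n = n,
          r_partial = NA_real_, z = unname(cf[, "Estimate"]),
          v = unname(cf[, "Std. Error"]^2)
        ))
      }
      tval <- cf[, "t value"]
      df <- n - p - 1
      r <- tval / sqrt(tval^2 + df)
      if (any(abs(r) >= 1 - 1e-8)) {
        warning("partial correlation numerically at +-1 clamped",
                call. = FALSE)
        r <- pmin(pmax(r, -(1 - 1e-8)), 1 - 1e-8)
      }
      tibble::tibble(
        study_id = key$study_id,
        predictor = seq_len(p),
        n = n,
        r_partial = as.numeric(r),
        z = atanh(as.numeric(r)),
        v = 1 / (n - (p - 1) - 3)
      )
    }) |>
    dplyr::bind_rows()
}

meta_priors_default <- list(mu_var = 10, tau_scale = 0.5, beta_var = 10)

# The hierarchical normal-normal models are sampled in their exactly
# equivalent marginalized form (study effects theta_k integrated out):
# z_k ~ N(mu [+ b m_k], v_k + tau^2). The (mu, tau) posterior is identical
# to the centered hierarchical parameterization but mixes well even as
# tau -> 0, where the centered form's Gibbs updates become arbitrarily slow.
jags_meta_random <- "
model {
  for (k in 1:K) {
    z[k] ~ dnorm(mu, 1 / (v[k] + pow(tau, 2)))
  }
  mu ~ dnorm(0, 1 / mu_var)
  tau ~ dnorm(0, pow(tau_scale, -2)) T(0,)
  tau2 <- pow(tau, 2)
}"

jags_meta_mixed <- "
model {
  for (k in 1:K) {
    z[k] ~ dnorm(mu + beta_m * m[k], 1 / (v[k] + pow(tau, 2)))
  }
  mu ~ dnorm(0, 1 / mu_var)
  beta_m ~ dnorm(0, 1 / beta_var)
  tau ~ dnorm(0, pow(tau_scale, -2)) T(0,)
  tau2 <- pow(tau, 2)
}"

#' Hierarchical Bayesian random-effects meta-analysis
#'
#' Fits z_k ~ N(theta_k, v_k), theta_k ~ N(mu, tau^2) to the Fisher-z effect
#' sizes of one predictor, with weakly informative hyperpriors
#' mu ~ N(0, variance `mu_var`) and tau ~ half-normal(scale `tau_scale`)
#' chosen to remain stable down to K = 3 studies. The pooled effect is
#' summarized by its posterior mean and SD; the between-study heterogeneity
#' tau^2 by its posterior median (its posterior is right-skewed).
#'
#' @param records Tibble of effect sizes for a single predictor with columns
#'   `z` and `v` (see [effect_sizes()]); at least 2 rows.
#' @param mcmc A [mcmc_config()].
#' @param mu_var,tau_scale Hyperprior settings.
#' @return A tibble row: `mu_z`, `se_z`, `tau2`, `tau2_lo`, `tau2_hi` (the
#'   central 95% credible interval of tau^2), `max_rhat`, `min_ess`,
#'   `converged`.
#' @export
meta_random <- function(records, mcmc = mcmc_config(),
                        mu_var = meta_priors_default$mu_var,
                        tau_scale = meta_priors_default$tau_scale) {
  check_meta_records(records)
  fit <- run_jags(
    jags_meta_random,
    data = list(z = records$z, v = records$v, K = nrow(records),
                mu_var = mu_var, tau_scale = tau_scale),
    monitor = c("mu", "tau2"),
    mcmc = mcmc
  )
  sm <- fit$summary
  tau2_draws <- as.matrix(fit$samples)[, "tau2"]
  ci <- quantile(tau2_draws, c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    mu_z = sm$estimate[sm$term == "mu"],
    se_z = sm$std.error[sm$term == "mu"],
    tau2 = sm$median[sm$term == "tau2"],
    tau2_lo = ci[1],
    tau2_hi = ci[2],
    max_rhat = max(sm$rhat, na.rm = TRUE),
    min_ess = min(sm$ess, na.rm = TRUE),
    converged = fit$converged
  )
}

#' Hierarchical Bayesian mixed-effects meta-analysis
#'
#' Extends [meta_random()] with a study-level moderator in the mean
#' structure, theta_k ~ N(mu + b m_k, tau_res^2). The residual heterogeneity
#' tau_res^2 is the posterior median of the variance component; the
#' moderator-explained heterogeneity is delta_tau2 = max(0, tau2 - tau_res^2)
#' where tau2 comes from the random-effects model on the same records
#' (truncated at zero when the moderator explains nothing).
#'
#' @inheritParams meta_random
#' @param moderators Numeric vector of study-level moderator values aligned
#'   with `records` rows, or a tibble with columns `study_id`, `m`.
#' @param tau2 Between-study heterogeneity from the random-effects model; if
#'   `NULL` it is computed by calling [meta_random()] on `records`.
#' @param beta_var Prior variance of the moderator coefficient.
#' @return A tibble row: `mu_z`, `se_z`, `tau2`, `tau2_res`, `delta_tau2`,
#'   `max_rhat`, `min_ess`, `converged`.
#' @export
meta_mixed <- function(records, moderators, mcmc = mcmc_config(), tau2 = NULL,
                       mu_var = meta_priors_default$mu_var,
                       tau_scale = meta_priors_default$tau_scale,
                       beta_var = meta_priors_default$beta_var) {
  check_meta_records(records)
  m <- align_moderators(records, moderators)
  if (is.null(tau2)) {
    re <- meta_random(records, mcmc = mcmc, mu_var = mu_var,
                      tau_scale = tau_scale)
    tau2 <- re$tau2
  }
  fit <- run_jags(
    jags_meta_mixed,
    data = list(z = records$z, v = records$v, m = m, K = nrow(records),
                mu_var = mu_var, tau_scale = tau_scale, beta_var = beta_var),
    monitor = c("mu", "beta_m", "tau2"),
    mcmc = mcmc
  )
  sm <- fit$summary
  tau2_res <- sm$median[sm$term == "tau2"]
  tibble::tibble(
    mu_z = sm$estimate[sm$term == "mu"],
    se_z = sm$std.error[sm$term == "mu"],
    tau2 = tau2,
    tau2_res = tau2_res,
    delta_tau2 = max(0, tau2 - tau2_res),
    max_rhat = max(sm$rhat, na.rm = TRUE),
    min_ess = min(sm$ess, na.rm = TRUE),
    converged = fit$converged
  )
}

check_meta_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("z", "v") %in% names(records)))
  if (nrow(records) < 2) {
    stop("meta-analysis needs at least 2 studies", call. = FALSE)
  }
  if (any(records$v <= 0)) stop("sampling variances must be > 0", call. = FALSE)
  invisible(records)
}

align_moderators <- function(records, moderators) {
  if (is.data.frame(moderators)) {
    stopifnot(all(c("study_id", "m") %in% names(moderators)))
    idx <- match(records$study_id, moderators$study_id)
    if (anyNA(idx)) stop("moderator table missing some studies", call. = FALSE)
    m <- moderators$m[idx]
  } else {
    m <- as.numeric(moderators)
  }
  if (length(m) != nrow(records)) {
    stop("moderators must align with the effect-size records", call. = FALSE)
  }
  m
}

#' Per-predictor heterogeneity summaries for a study database
#'
#' Runs [effect_sizes()], then for each predictor a random-effects
#' meta-analysis (pooled effect mu_z, its SE, and tau2) and — when moderators
#' are available — the matching mixed-effects model (tau_res^2 and
#' delta_tau2). These are the per-predictor heterogeneity inputs of the
#' similarity measure and the hyperparameters of the informative priors.
#'
#' @param db A `swip_database` or stacked study tibble.
#' @param moderators Optional tibble `study_id`, `m` (taken from the database
#'   object if present there).
#' @param mcmc A [mcmc_config()].
#' @param ... Passed to [meta_random()] and [meta_mixed()].
#' @return A tibble with one row per predictor: `predictor`, `mu_z`, `se_z`,
#'   `tau2`, `tau2_res`, `delta_tau2`, `max_rhat`, `min_ess`, `converged`
#'   (`tau2_res`/`delta_tau2` are `NA` without moderators).
#' @export
heterogeneity_summaries <- function(db, moderators = NULL,
                                    mcmc = mcmc_config(), ...) {
  if (is.null(moderators) && inherits(db, "swip_database")) {
    moderators <- db$moderators
  }
  es <- effect_sizes(db)
  es |>
    dplyr::group_by(.data$predictor) |>
    dplyr::group_map(function(recs, key) {
      sub_mcmc <- mcmc
      sub_mcmc$seed <- derive_seed(mcmc$seed, key$predictor)
      re <- meta_random(recs, mcmc = sub_mcmc, ...)
      if (is.null(moderators)) {
        out <- dplyr::mutate(re, tau2_res = NA_real_, delta_tau2 = NA_real_)
      } else {
        sub_mcmc$seed <- derive_seed(mcmc$seed, key$predictor + 1000L)
        me <- meta_mixed(recs, moderators, mcmc = sub_mcmc, tau2 = re$tau2, ...)
        out <- tibble::tibble(
          mu_z = re$mu_z, se_z = re$se_z, tau2 = re$tau2,
          tau2_res = me$tau2_res, delta_tau2 = me$delta_tau2,
          max_rhat = max(re$max_rhat, me$max_rhat),
          min_ess = min(re$min_ess, me$min_ess),
          converged = re$converged && me$converged
        )
      }
      dplyr::mutate(out, predictor = key$predictor, .before = 1)
    }) |>
    dplyr::bind_rows()
}
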