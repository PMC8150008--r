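#' MCMC sampler settings
#'
#' Settings shared by all JAGS-based fits: the study default is four chains
#' of 2,000 iterations each with the first 1,000 discarded as burn-in, and
#' convergence declared when every parameter's Gelman-Rubin statistic is
#' below 1.02.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Total iterations per chain.
#' @param warmup Burn-in iterations discarded from each chain.
#' @param rhat_threshold Convergence bound on the Gelman-Rubin statistic.
#' @param seed Integer seed for the sampler (chain seeds are derived from it).
#' @return An object of class `swip_mcmc` (a named list).
#' @export
mcmc_config <- function(chains = 4, iterations = 2000, warmup = 1000,
                        rhat_threshold = 1.02, seed = 1L) {
  if (chains < 2) stop("`chains` must be >= 2", call. = FALSE)
  if (warmup >= iterations) {
    stop("`warmup` must be smaller than `iterations`", call. = FALSE)
  }
  structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         warmup = as.integer(warmup), rhat_threshold = rhat_threshold,
         seed = as.integer(seed)),
    class = "swip_mcmc"
  )
}

# Run a JAGS model with per-chain seeded RNGs, monitor the given nodes, and
# summarize posterior mean/SD, split-free Gelman-Rubin R-hat and effective
# sample size per parameter. If any R-hat exceeds the threshold the model is
# rerun once with doubled iterations; a still-unconverged result is returned
# flagged, never silently.
run_jags <- function(model, data, monitor, mcmc, inits = NULL) {
  sample_once <- function(iterations, warmup, seed_off) {
    ini <- lapply(seq_len(mcmc$chains), function(ch) {
      c(list(.RNG.name = "base::Mersenne-Twister",
             .RNG.seed = derive_seed(mcmc$seed, ch + seed_off)),
        inits %||% list())
    })
    jm <- rjags::jags.model(textConnection(model), data = data,
                            inits = ini, n.chains = mcmc$chains,
                            quiet = TRUE)
    update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitor, iterations - warmup,
                        progress.bar = "none")
  }
  s <- sample_once(mcmc$iterations, mcmc$warmup, 0L)
  sm <- summarize_chains(s)
  retried <- FALSE
  if (any(sm$rhat > mcmc$rhat_threshold, na.rm = TRUE)) {
    retried <- TRUE
    s <- sample_once(2L * mcmc$iterations, 2L * mcmc$warmup, 100L)
    sm <- summarize_chains(s)
  }
  converged <- !any(sm$rhat > mcmc$rhat_threshold, na.rm = TRUE)
  list(samples = s, summary = sm, converged = converged, retried = retried)
}

summarize_chains <- function(samples) {
  draws <- as.matrix(samples)
  rhat <- tryCatch(
    coda::gelman.diag(samples, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(draws))
  )
  ess <- coda::effectiveSize(samples)
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    median = unname(apply(draws, 2, median)),
    rhat = as.numeric(rhat[colnames(draws)]),
    ess = as.numeric(ess[colnames(draws)])
  )
}
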