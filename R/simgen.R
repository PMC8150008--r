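#' True generating parameters for a simulated focal study
#'
#' Bundles the quantities that define one simulated research situation: the
#' focal study's true regression coefficients, the meta-analytic mean
#' coefficients around which previous studies scatter, the error variance and
#' the focal sample size. Defaults are the simulation-study values: three
#' predictors with focal coefficients (0.5, 0.25, -0.5) representing
#' certainty, disagreement and contradiction relative to the meta-analytic
#' means (0.4, 0, 0.3), unit error variance, and a focal sample of 200.
#'
#' @param beta_f Numeric vector of true focal-study coefficients (length p).
#' @param mu_beta Numeric vector of meta-analytic mean coefficients (length p).
#' @param sigma2 Error variance of the regression, > 0.
#' @param n_f Focal-study sample size; must be at least p + 4.
#' @return An object of class `swip_params` (a named list).
#' @export
#' @examples
#' sim_params()
sim_params <- function(beta_f = c(0.5, 0.25, -0.5),
                       mu_beta = c(0.4, 0, 0.3),
                       sigma2 = 1,
                       n_f = 200) {
  if (length(beta_f) != length(mu_beta)) {
    stop("`beta_f` and `mu_beta` must have the same length", call. = FALSE)
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  p <- length(beta_f)
  if (n_f < p + 4) stop("`n_f` must be at least p + 4", call. = FALSE)
  structure(
    list(beta_f = as.numeric(beta_f), mu_beta = as.numeric(mu_beta),
         sigma2 = as.numeric(sigma2), n_f = as.integer(n_f), p = p),
    class = "swip_params"
  )
}

#' Enumerate a simulation design grid
#'
#' Builds the full Cartesian product of the design factors: number of previous
#' studies K, sample-size offset delta_n (mean previous-study size minus the
#' focal size), predictor mean offset delta_mu, and between-study
#' heterogeneity tau2. Each condition receives a deterministic, distinct seed
#' derived from `base_seed` and its row index, so conditions are reproducible
#' independently of execution order. The default levels are the 210-condition
#' study design (3 x 2 x 5 x 7).
#'
#' @param levels_k Integer levels for the number of previous studies (each >= 2).
#' @param levels_dn Signed integer levels for the sample-size offset.
#' @param levels_dmu Non-negative levels for the predictor mean offset.
#' @param levels_tau2 Positive levels for the between-study heterogeneity.
#' @param moderator_r2 Fraction of tau2 explained by the simulated moderator.
#' @param n_reps Replications per condition.
#' @param base_seed Integer seed from which condition seeds are derived.
#' @return A tibble with one row per condition: `condition`, the four factor
#'   columns, `moderator_r2`, `n_reps`, `seed`.
#' @export
#' @examples
#' nrow(sim_grid()) # 210
#' sim_grid(levels_k = 3, levels_dn = 0, levels_dmu = 1, levels_tau2 = 0.1)
sim_grid <- function(levels_k = c(3, 5, 10),
                     levels_dn = c(-100, 100),
                     levels_dmu = c(0.25, 0.5, 1, 2, 3),
                     levels_tau2 = c(0.025, 0.05, 0.10, 0.15, 0.20, 0.35, 0.5),
                     moderator_r2 = 0.1,
                     n_reps = 100,
                     base_seed = 20210511) {
  levs <- list(levels_k, levels_dn, levels_dmu, levels_tau2)
  if (any(lengths(levs) == 0L)) {
    stop("all factor level vectors must be non-empty", call. = FALSE)
  }
  if (any(levels_k < 2)) stop("`levels_k` must all be >= 2", call. = FALSE)
  if (any(levels_tau2 <= 0)) stop("`levels_tau2` must be positive", call. = FALSE)
  if (moderator_r2 < 0 || moderator_r2 >= 1) {
    stop("`moderator_r2` must be in [0, 1)", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    k = as.integer(sort(levels_k)),
    delta_n = as.integer(sort(levels_dn)),
    delta_mu = sort(levels_dmu),
    tau2 = sort(levels_tau2)
  )
  grid |>
    dplyr::mutate(
      condition = dplyr::row_number(),
      moderator_r2 = moderator_r2,
      n_reps = as.integer(n_reps),
      seed = derive_seed(base_seed, dplyr::row_number()),
      .before = 1
    ) |>
    dplyr::relocate("condition")
}

#' Per-replication dataset manifest for a design grid
#'
#' Expands a condition grid into one row per (condition, replication) with a
#' deterministic replication seed. With the default 210-condition grid at 100
#' replications this enumerates the study's 21,000 generated datasets without
#' materializing any of them.
#'
#' @param grid A tibble from [sim_grid()].
#' @param n_reps Optional override of the per-condition replication count.
#' @return A tibble with columns of `grid` plus `rep` and `rep_seed`.
#' @export
sim_manifest <- function(grid, n_reps = NULL) {
  stopifnot(is.data.frame(grid), all(c("condition", "seed") %in% names(grid)))
  reps <- n_reps %||% grid$n_reps
  grid |>
    dplyr::mutate(n_reps = as.integer(reps)) |>
    tidyr::uncount(.data$n_reps, .remove = FALSE, .id = "rep") |>
    dplyr::mutate(rep_seed = derive_seed(.data$seed, .data$rep))
}

#' Simulate the focal study's dataset
#'
#' Draws the p predictors column-wise from standard normal distributions and
#' the outcome from the linear model y = X beta_f + e with e ~ N(0, sigma2)
#' and zero intercept.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble with columns `study_id` ("focal"), `y`, `x1`..`xp`.
#' @export
#' @examples
#' focal <- simulate_focal(sim_params(), seed = 1)
#' dim(focal)
simulate_focal <- function(params, seed = NULL) {
  stopifnot(inherits(params, "swip_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_f
  p <- params$p
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% params$beta_f + rnorm(n, sd = sqrt(params$sigma2)))
  out <- tibble::as_tibble(as.data.frame(X, col.names = paste0("x", seq_len(p))))
  names(out) <- paste0("x", seq_len(p))
  dplyr::bind_cols(tibble::tibble(study_id = "focal", y = y), out)
}

#' Simulate the database of previously conducted studies
#'
#' For each of the K previous studies: the sample size is drawn from
#' N(n_f + delta_n, variance 25) rounded to the nearest integer with floor
#' p + 4; a study-level moderator m_k is drawn standard normal; the study's
#' true coefficient vector is mu_beta + gamma * m_k + e_k with
#' gamma = sqrt(moderator_r2 * tau2) and independent coordinate noise
#' e_k ~ N(0, tau2), so the moderator adds variance on top of tau2 (total
#' coefficient variance (1 + moderator_r2) * tau2, residual tau2); predictors
#' are drawn from N(delta_mu, 1); and the outcome follows the regression with
#' unit error variance and zero intercept.
#'
#' @param condition A single-row tibble (or list) with fields `k`, `delta_n`,
#'   `delta_mu`, `tau2`, `moderator_r2` as produced by [sim_grid()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return An object of class `swip_database`: a list with `studies` (one
#'   tibble, all studies stacked, columns `study_id`, `y`, `x1`..`xp`),
#'   `moderators` (tibble `study_id`, `m`) and `true_betas` (tibble
#'   `study_id`, `predictor`, `beta`; retained for evaluation only).
#' @export
#' @examples
#' cond <- sim_grid(levels_k = 3, levels_dn = 0, levels_dmu = 0.5,
#'                  levels_tau2 = 0.05)[1, ]
#' db <- simulate_database(cond, sim_params(), seed = 2)
#' db$studies
simulate_database <- function(condition, params, seed = NULL) {
  stopifnot(inherits(params, "swip_params"))
  cond <- as.list(condition)
  needed <- c("k", "delta_n", "delta_mu", "tau2", "moderator_r2")
  if (!all(needed %in% names(cond))) {
    stop("`condition` must provide ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (cond$tau2 <= 0) stop("`tau2` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(cond$k)
  p <- params$p
  gamma <- sqrt(cond$moderator_r2 * cond$tau2)
  ids <- sprintf("prev%02d", seq_len(K))

  m <- rnorm(K)
  studies <- vector("list", K)
  betas <- matrix(NA_real_, K, p)
  for (k in seq_len(K)) {
    n_k <- max(p + 4L, as.integer(round(rnorm(1, params$n_f + cond$delta_n, 5))))
    beta_k <- params$mu_beta + gamma * m[k] + rnorm(p, sd = sqrt(cond$tau2))
    betas[k, ] <- beta_k
    X <- matrix(rnorm(n_k * p, mean = cond$delta_mu), n_k, p)
    y <- as.numeric(X %*% beta_k + rnorm(n_k))
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- paste0("x", seq_len(p))
    studies[[k]] <- dplyr::bind_cols(
      tibble::tibble(study_id = ids[k], y = y), df
    )
  }
  structure(
    list(
      studies = dplyr::bind_rows(studies),
      moderators = tibble::tibble(study_id = ids, m = m),
      true_betas = tibble::tibble(
        study_id = rep(ids, each = p),
        predictor = rep(seq_len(p), K),
        beta = as.numeric(t(betas))
      )
    ),
    class = "swip_database"
  )
}

#' @export
print.swip_database <- function(x, ...) {
  k <- length(unique(x$studies$study_id))
  p <- length(predictor_cols(x$studies))
  cat(sprintf("<swip_database> %d studies, %d predictors, %d rows total\n",
              k, p, nrow(x$studies)))
  invisible(x)
}

#' @export
print.swip_params <- function(x, ...) {
  cat("<swip_params>\n")
  cat("  beta_f :", paste(format(x$beta_f), collapse = ", "), "\n")
  cat("  mu_beta:", paste(format(x$mu_beta), collapse = ", "), "\n")
  cat(sprintf("  sigma2 : %s   n_f: %d\n", format(x$sigma2), x$n_f))
  invisible(x)
}
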