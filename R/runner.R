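#' Shrinkage of a posterior estimate toward the meta-analytic mean
#'
#' Displacement of the estimate from the focal study's true coefficient,
#' `beta_hat - beta_true`. With this sign convention shrinkage is negative
#' when the meta-analytic mean lies below the focal value (the estimate is
#' pulled down) and positive when it lies above, matching the direction the
#' informative prior pulls in.
#'
#' @param beta_true True focal-study coefficient(s).
#' @param beta_hat Posterior estimate(s).
#' @return `beta_hat - beta_true`, vectorized.
#' @export
#' @examples
#' shrinkage(-0.5, -0.2) # pulled up toward a meta mean of 0.3: +0.3
#' shrinkage(0.5, 0.45)  # pulled down toward 0.4: -0.05
shrinkage <- function(beta_true, beta_hat) {
  stopifnot(is.numeric(beta_true), is.numeric(beta_hat),
            all(is.finite(beta_true)), all(is.finite(beta_hat)))
  beta_hat - beta_true
}

#' Select conditions spanning the corners of a design grid
#'
#' Returns the 2 x 2 x 2 corners of (K, delta_mu, tau2) — the factors the
#' similarity measure responds to — with the sample-size offset delta_n
#' alternating between its extremes across the eight cells. Used for
#' scaled-down reruns of the full study.
#'
#' @param grid A tibble from [sim_grid()].
#' @return A tibble of (up to) 8 rows of `grid`.
#' @export
grid_corners <- function(grid) {
  stopifnot(all(c("k", "delta_n", "delta_mu", "tau2") %in% names(grid)))
  corners <- tidyr::expand_grid(
    k = range(grid$k), delta_mu = range(grid$delta_mu),
    tau2 = range(grid$tau2)
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(delta_n = range(grid$delta_n)[(dplyr::row_number() %% 2) + 1])
  grid |>
    dplyr::inner_join(corners, by = c("k", "delta_n", "delta_mu", "tau2"))
}

#' Run all replications of one simulation condition
#'
#' For each replication: generates the focal dataset and the database of
#' previous studies, computes the average generalizability index B-bar, runs
#' the per-predictor random- and mixed-effects meta-analyses, forms the
#' similarity weights, and fits the requested analysis arms. Replication
#' seeds are derived from the condition seed, so results do not depend on
#' execution order. A crashing replication is logged and excluded, never
#' fatal to the condition.
#'
#' @param condition One-row tibble from [sim_grid()].
#' @param params A [sim_params()].
#' @param arms Character subset of `c("pooled", "npp", "map", "swip")`.
#' @param mcmc A [mcmc_config()].
#' @param n_reps Optional override of `condition$n_reps`.
#' @return An object of class `swip_condition_result`: list with
#'   `condition`, `estimates` (rep x arm x term posterior summaries),
#'   `similarity` (rep x predictor omega components), `aggregate`
#'   (per arm x coefficient averages: mean estimate, root-mean-square SE,
#'   shrinkage), `similarity_aggregate`, `n_completed`, `failures`,
#'   `max_rhat`.
#' @export
run_condition <- function(condition, params = sim_params(),
                          arms = c("pooled", "npp", "map", "swip"),
                          mcmc = mcmc_config(), n_reps = NULL) {
  arms <- match.arg(arms, several.ok = TRUE)
  cond <- as.list(condition)
  reps <- as.integer(n_reps %||% cond$n_reps)
  if (reps < 1) stop("need at least one replication", call. = FALSE)
  p <- params$p

  rep_out <- vector("list", reps)
  failures <- character(0)
  for (r in seq_len(reps)) {
    seed_r <- derive_seed(cond$seed %||% 1L, r)
    res <- tryCatch(
      run_one_replication(cond, params, arms, mcmc, r, seed_r),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("rep %d: %s", r, conditionMessage(res)))
    } else {
      rep_out[[r]] <- res
    }
  }
  done <- !vapply(rep_out, is.null, logical(1))
  estimates <- dplyr::bind_rows(lapply(rep_out[done], `[[`, "estimates"))
  similarity <- dplyr::bind_rows(lapply(rep_out[done], `[[`, "similarity"))

  truth <- tibble::tibble(term = paste0("x", seq_len(p)),
                          beta_true = params$beta_f)
  if (nrow(estimates) == 0L) {
    return(structure(
      list(condition = tibble::as_tibble(condition),
           estimates = estimates, similarity = similarity,
           aggregate = tibble::tibble(), similarity_aggregate = tibble::tibble(),
           n_completed = 0L, failures = failures, max_rhat = NA_real_),
      class = "swip_condition_result"
    ))
  }
  aggregate <- estimates |>
    dplyr::group_by(.data$arm, .data$term) |>
    dplyr::summarise(
      estimate = mean(.data$estimate),
      std.error = sqrt(mean(.data$std.error^2)),
      max_rhat = max(.data$rhat, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(truth, by = "term") |>
    dplyr::mutate(shrinkage = NA_real_)
  has_truth <- !is.na(aggregate$beta_true)
  aggregate$shrinkage[has_truth] <- shrinkage(aggregate$beta_true[has_truth],
                                              aggregate$estimate[has_truth])
  sim_agg <- if (nrow(similarity)) {
    similarity |>
      dplyr::group_by(.data$predictor) |>
      dplyr::summarise(
        b_bar = mean(.data$b_bar), tau2 = mean(.data$tau2),
        delta_tau2 = mean(.data$delta_tau2), omega = mean(.data$omega),
        .groups = "drop"
      )
  } else {
    tibble::tibble()
  }
  structure(
    list(
      condition = tibble::as_tibble(condition),
      estimates = estimates,
      similarity = similarity,
      aggregate = aggregate,
      similarity_aggregate = sim_agg,
      n_completed = sum(done),
      failures = failures,
      max_rhat = if (nrow(estimates)) max(estimates$rhat, na.rm = TRUE) else NA_real_
    ),
    class = "swip_condition_result"
  )
}

run_one_replication <- function(cond, params, arms, mcmc, r, seed_r) {
  focal <- simulate_focal(params, seed = derive_seed(seed_r, 1L))
  db <- simulate_database(cond, params, seed = derive_seed(seed_r, 2L))
  mc <- mcmc
  mc$seed <- derive_seed(seed_r, 3L)

  needs_meta <- any(arms %in% c("map", "swip"))
  needs_bbar <- "swip" %in% arms
  meta <- if (needs_meta) heterogeneity_summaries(db, mcmc = mc) else NULL
  sim_tbl <- tibble::tibble()
  weights <- NULL
  if (needs_bbar) {
    # separation between strongly shifted samples is an anticipated design
    # point here (it just drives B toward 0), so the fallback's warning is
    # muffled inside the runner
    bbar <- withCallingHandlers(
      generalizability_index(focal, db),
      warning = function(w) {
        if (grepl("separation detected", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    weights <- similarity_weights(meta, bbar)
    sim_tbl <- dplyr::mutate(weights, rep = r, .before = 1)
  }

  fits <- list()
  for (arm in arms) {
    mc_arm <- mc
    mc_arm$seed <- derive_seed(mc$seed, match(arm, c("pooled", "npp", "map", "swip")))
    fits[[arm]] <- switch(arm,
      pooled = fit_pooled(focal, db, mcmc = mc_arm),
      npp = fit_npp(focal, db, mcmc = mc_arm),
      map = fit_map(focal, meta, mcmc = mc_arm),
      swip = fit_swip(focal, swip_prior(meta, weights), mcmc = mc_arm)
    )
  }
  estimates <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::mutate(f$summary[c("term", "estimate", "std.error", "rhat", "ess")],
                  arm = f$arm, rep = r, converged = f$converged,
                  .before = 1)
  }))
  list(estimates = estimates, similarity = sim_tbl)
}

#' @export
print.swip_condition_result <- function(x, ...) {
  cat(sprintf("<swip_condition_result> %d/%s replications, max R-hat %.4f\n",
              x$n_completed,
              as.character(x$condition$n_reps %||% x$n_completed),
              x$max_rhat))
  print(x$aggregate)
  invisible(x)
}

#' Run a simulation study over a design grid
#'
#' Maps [run_condition()] over the rows of a condition grid and binds the
#' aggregates. Conditions are independent work units with seeds bound to
#' (condition, replication), so results are identical regardless of
#' execution order.
#'
#' @param grid A tibble from [sim_grid()] (or a subset of its rows).
#' @param params A [sim_params()].
#' @inheritParams run_condition
#' @param keep_replications Keep per-replication estimates in the result.
#' @param verbose Print a line per condition.
#' @return An object of class `swip_study`: list with `conditions` (the
#'   grid), `aggregate` (condition x arm x term), `similarity` (condition x
#'   predictor means), `replications` (optional), `max_rhat`, `failures`.
#' @export
run_study <- function(grid, params = sim_params(),
                      arms = c("pooled", "npp", "map", "swip"),
                      mcmc = mcmc_config(), n_reps = NULL,
                      keep_replications = FALSE, verbose = FALSE) {
  stopifnot(nrow(grid) >= 1)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (verbose) {
      message(sprintf("condition %d/%d (K=%d, dN=%+d, dMu=%.2f, tau2=%.3f)",
                      i, nrow(grid), grid$k[i], grid$delta_n[i],
                      grid$delta_mu[i], grid$tau2[i]))
    }
    res[[i]] <- run_condition(grid[i, ], params, arms, mcmc, n_reps = n_reps)
  }
  agg <- dplyr::bind_rows(lapply(res, function(x) {
    dplyr::mutate(x$aggregate, condition = x$condition$condition, .before = 1)
  }))
  sim <- dplyr::bind_rows(lapply(res, function(x) {
    if (nrow(x$similarity_aggregate)) {
      dplyr::mutate(x$similarity_aggregate,
                    condition = x$condition$condition, .before = 1)
    } else {
      tibble::tibble()
    }
  }))
  structure(
    list(
      conditions = grid,
      aggregate = agg,
      similarity = sim,
      replications = if (keep_replications) {
        dplyr::bind_rows(lapply(res, function(x) {
          dplyr::mutate(x$estimates, condition = x$condition$condition,
                        .before = 1)
        }))
      } else {
        NULL
      },
      max_rhat = max(vapply(res, `[[`, numeric(1), "max_rhat"), na.rm = TRUE),
      failures = unlist(lapply(res, `[[`, "failures"))
    ),
    class = "swip_study"
  )
}

#' @export
print.swip_study <- function(x, ...) {
  cat(sprintf("<swip_study> %d conditions, max R-hat %.4f, %d failures\n",
              nrow(x$conditions), x$max_rhat, length(x$failures)))
  print(head(x$aggregate, 10))
  invisible(x)
}

#' Linear models summarizing the behavior of the similarity measure
#'
#' Fits two ordinary least-squares models across the grid of a completed
#' study: (1) mean omega on the designed total heterogeneity
#' (1 + moderator_r2) * tau2 and the predictor mean offset delta_mu —
#' expected slopes are both negative; and (2) the mean absolute shrinkage of
#' the SWIP estimates on mean omega — expected slope positive (more similar
#' studies pull the estimates harder toward their meta-analytic means).
#'
#' @param study A `swip_study` whose arms include `"swip"` and whose
#'   similarity table is non-empty; needs at least 2 grid cells.
#' @return A tibble of coefficients: `model`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
behavior_models <- function(study) {
  stopifnot(inherits(study, "swip_study"))
  if (nrow(study$conditions) < 2) {
    stop("need at least 2 grid cells", call. = FALSE)
  }
  if (!nrow(study$similarity)) {
    stop("study has no similarity results (was the swip arm run?)",
         call. = FALSE)
  }
  des <- study$conditions |>
    dplyr::mutate(total_het = (1 + .data$moderator_r2) * .data$tau2) |>
    dplyr::select("condition", "total_het", "delta_mu")
  om <- study$similarity |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(omega = mean(.data$omega), .groups = "drop") |>
    dplyr::left_join(des, by = "condition")
  shr <- study$aggregate |>
    dplyr::filter(.data$arm == "swip", !is.na(.data$shrinkage)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(abs_shrinkage = mean(abs(.data$shrinkage)),
                     .groups = "drop") |>
    dplyr::left_join(om[, c("condition", "omega")], by = "condition")
  fit_tidy <- function(fit, label) {
    cf <- summary(fit)$coefficients
    tibble::tibble(model = label, term = rownames(cf),
                   estimate = unname(cf[, 1]), std.error = unname(cf[, 2]),
                   statistic = unname(cf[, 3]), p.value = unname(cf[, 4]))
  }
  m1 <- tryCatch(lm(omega ~ total_het + delta_mu, data = om),
                 error = function(e) NULL)
  m2 <- if (nrow(shr)) lm(abs_shrinkage ~ omega, data = shr) else NULL
  out <- dplyr::bind_rows(
    if (!is.null(m1)) fit_tidy(m1, "omega ~ total_het + delta_mu"),
    if (!is.null(m2)) fit_tidy(m2, "abs_shrinkage ~ omega")
  )
  if (!nrow(out)) stop("no behavior model could be fit", call. = FALSE)
  out
}
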