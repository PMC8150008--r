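#' Tidy a fitted regression arm
#'
#' @param x A `swip_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`
#'   (posterior mean), `std.error` (posterior SD), `median`, `rhat`, `ess`.
#' @method tidy swip_fit
#' @export
tidy.swip_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a fitted regression arm
#'
#' @param x A `swip_fit`.
#' @param ... Unused.
#' @return A tibble row: `arm`, `n`, `p`, `max_rhat`, `min_ess`,
#'   `converged`, `retried`.
#' @method glance swip_fit
#' @export
glance.swip_fit <- function(x, ...) {
  tibble::tibble(
    arm = x$arm, n = x$n, p = x$p,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE),
    converged = x$converged, retried = x$retried
  )
}

#' Tidy a generalizability result
#'
#' @param x A `swip_bbar`.
#' @param ... Unused.
#' @return The per-study tibble (`study_id`, `B`, `penalized`).
#' @method tidy swip_bbar
#' @export
tidy.swip_bbar <- function(x, ...) {
  x$per_study
}

#' One-row summary of a generalizability result
#'
#' @param x A `swip_bbar`.
#' @param ... Unused.
#' @return A tibble row: `b_bar`, `k`, `min_b`, `max_b`.
#' @method glance swip_bbar
#' @export
glance.swip_bbar <- function(x, ...) {
  tibble::tibble(
    b_bar = x$b_bar, k = nrow(x$per_study),
    min_b = min(x$per_study$B), max_b = max(x$per_study$B)
  )
}

#' Tidy a condition result
#'
#' @param x A `swip_condition_result`.
#' @param ... Unused.
#' @return The aggregate tibble (arm x term averages and shrinkage).
#' @method tidy swip_condition_result
#' @export
tidy.swip_condition_result <- function(x, ...) {
  x$aggregate
}

#' One-row summary of a condition result
#'
#' @param x A `swip_condition_result`.
#' @param ... Unused.
#' @return A tibble row: condition factors, `n_completed`, `n_failed`,
#'   `max_rhat`.
#' @method glance swip_condition_result
#' @export
glance.swip_condition_result <- function(x, ...) {
  dplyr::bind_cols(
    x$condition[intersect(c("condition", "k", "delta_n", "delta_mu", "tau2"),
                          names(x$condition))],
    tibble::tibble(n_completed = x$n_completed,
                   n_failed = length(x$failures),
                   max_rhat = x$max_rhat)
  )
}

#' Tidy a simulation study
#'
#' @param x A `swip_study`.
#' @param ... Unused.
#' @return The aggregate tibble (condition x arm x term).
#' @method tidy swip_study
#' @export
tidy.swip_study <- function(x, ...) {
  x$aggregate
}

#' One-row summary of a simulation study
#'
#' @param x A `swip_study`.
#' @param ... Unused.
#' @return A tibble row: `n_conditions`, `n_arms`, `max_rhat`, `n_failed`.
#' @method glance swip_study
#' @export
glance.swip_study <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$conditions),
    n_arms = length(unique(x$aggregate$arm)),
    max_rhat = x$max_rhat,
    n_failed = length(x$failures)
  )
}
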