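#' Configuration of the similarity measure
#'
#' The similarity measure is a logistic function of the total heterogeneity
#' with maximum value `L`, midpoint `midpoint` and slope `slope`, multiplied
#' by the average generalizability index. The defaults (1, 0.24, 10) are
#' frozen to discriminate across the range of between-study heterogeneity
#' typical of psychological research (roughly 0.13 to 0.24); they are exposed
#' for sensitivity analysis only and never changed silently.
#'
#' @param L Maximum value of the logistic component.
#' @param midpoint Total heterogeneity at which the logistic component is L/2.
#' @param slope Steepness of the logistic decline.
#' @return An object of class `swip_omega_config`.
#' @export
omega_config <- function(L = 1, midpoint = 0.24, slope = 10) {
  if (midpoint <= 0) stop("`midpoint` must be positive", call. = FALSE)
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  structure(list(L = L, midpoint = midpoint, slope = slope),
            class = "swip_omega_config")
}

#' The similarity measure omega
#'
#' Combines between-study heterogeneity tau2, moderator-explained
#' heterogeneity delta_tau2, and the average generalizability index B-bar
#' into a single weight in `[0, 1]`:
#'
#'   omega = B-bar * L / (1 + exp(slope * (tau2 + delta_tau2 - midpoint)))
#'
#' omega is strictly decreasing in the total heterogeneity, linear in B-bar,
#' and non-compensatory: it never exceeds either B-bar or the logistic
#' component alone, so high sample similarity cannot offset heterogeneous
#' outcomes, nor vice versa.
#'
#' @param tau2,delta_tau2 Non-negative heterogeneity components (vectorized).
#' @param b_bar Average generalizability index in `[0, 1]`.
#' @param config An [omega_config()].
#' @return Numeric vector of similarity weights in `[0, 1]`.
#' @export
#' @examples
#' omega(0.24, 0, 1) # logistic midpoint: 0.5
#' omega(0.025, 0.0025, 0.9)
omega <- function(tau2, delta_tau2 = 0, b_bar = 1, config = omega_config()) {
  if (any(!is.finite(b_bar)) || any(b_bar < 0) || any(b_bar > 1)) {
    stop("`b_bar` must lie in [0, 1]", call. = FALSE)
  }
  if (any(tau2 < 0) || any(delta_tau2 < 0)) {
    stop("heterogeneity components must be non-negative", call. = FALSE)
  }
  total <- tau2 + delta_tau2
  b_bar * config$L / (1 + exp(config$slope * (total - config$midpoint)))
}

#' Per-predictor similarity weights
#'
#' Applies [omega()] to each predictor's heterogeneity summary, sharing the
#' focal-vs-database generalizability index B-bar across predictors (B-bar is
#' a property of the samples, not of any one coefficient).
#'
#' @param meta Per-predictor tibble from [heterogeneity_summaries()] with
#'   columns `predictor`, `tau2` and `delta_tau2` (`NA` delta_tau2 counts
#'   as 0).
#' @param bbar A `swip_bbar` object from [generalizability_index()], or a
#'   scalar B-bar.
#' @param config An [omega_config()].
#' @return A tibble with one row per predictor: `predictor`, `tau2`,
#'   `delta_tau2`, `b_bar`, `omega`.
#' @export
similarity_weights <- function(meta, bbar, config = omega_config()) {
  stopifnot(is.data.frame(meta),
            all(c("predictor", "tau2") %in% names(meta)))
  if (anyNA(meta$tau2)) stop("`tau2` missing for some predictor", call. = FALSE)
  b <- if (inherits(bbar, "swip_bbar")) bbar$b_bar else as.numeric(bbar)
  dt2 <- if ("delta_tau2" %in% names(meta)) {
    ifelse(is.na(meta$delta_tau2), 0, meta$delta_tau2)
  } else {
    rep(0, nrow(meta))
  }
  tibble::tibble(
    predictor = meta$predictor,
    tau2 = meta$tau2,
    delta_tau2 = dt2,
    b_bar = b,
    omega = omega(meta$tau2, dt2, b, config)
  )
}
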