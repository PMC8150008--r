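#' Plot posterior summaries of a fitted arm
#'
#' Posterior means with +-2 posterior-SD intervals for each parameter.
#'
#' @param object A `swip_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swip_fit
#' @export
autoplot.swip_fit <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$std.error,
                   xmax = .data$estimate + 2 * .data$std.error),
      height = 0.2
    ) +
    ggplot2::labs(
      x = "posterior mean ± 2 SD", y = NULL,
      title = sprintf("Posterior summaries (%s arm)", object$arm)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-study generalizability indices
#'
#' @param object A `swip_bbar`.
#' @param ... Unused.
#' @return A ggplot object with the per-study B values and their mean B-bar.
#' @method autoplot swip_bbar
#' @export
autoplot.swip_bbar <- function(object, ...) {
  ggplot2::ggplot(object$per_study,
                  ggplot2::aes(x = .data$study_id, y = .data$B)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = object$b_bar, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "generalizability index B", x = NULL,
                  title = sprintf("B-bar = %.3f", object$b_bar)) +
    ggplot2::theme_minimal()
}

#' Plot the behavior of the similarity measure across a study grid
#'
#' Mean similarity weight omega against the designed total heterogeneity
#' (1 + moderator_r2) * tau2, one line per predictor mean offset delta_mu —
#' the similarity analogue of the study's headline behavior figure.
#'
#' @param object A `swip_study` run with the `swip` arm.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swip_study
#' @export
autoplot.swip_study <- function(object, ...) {
  if (!nrow(object$similarity)) {
    stop("study has no similarity results to plot", call. = FALSE)
  }
  d <- object$similarity |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(omega = mean(.data$omega), .groups = "drop") |>
    dplyr::left_join(object$conditions, by = "condition") |>
    dplyr::mutate(total_het = (1 + .data$moderator_r2) * .data$tau2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_het, y = .data$omega,
                                  colour = factor(.data$delta_mu))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(tau^2 + delta * tau^2),
                  y = expression(omega), colour = expression(Delta[mu]),
                  title = "Similarity measure across the design grid") +
    ggplot2::theme_minimal()
}

#' Plot shrinkage against similarity across a study grid
#'
#' Per-condition, per-coefficient shrinkage of the SWIP estimates against
#' the condition's mean similarity weight.
#'
#' @param study A `swip_study` run with the `swip` arm.
#' @return A ggplot object.
#' @export
plot_shrinkage <- function(study) {
  stopifnot(inherits(study, "swip_study"))
  om <- study$similarity |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(omega = mean(.data$omega), .groups = "drop")
  d <- study$aggregate |>
    dplyr::filter(.data$arm == "swip", !is.na(.data$shrinkage)) |>
    dplyr::left_join(om, by = "condition")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega, y = .data$shrinkage,
                                  colour = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(omega), y = "shrinkage",
                  colour = "coefficient",
                  title = "Shrinkage toward the meta-analytic means") +
    ggplot2::theme_minimal()
}
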