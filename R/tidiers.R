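# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @describeIn calc_pm per-run PM estimates as a tibble.
#' @param x a `pm_estimate`.
#' @param ... unused.
#' @export
tidy.pm_estimate <- function(x, ...) {
  tibble::tibble(run = seq_along(x$run_values), pm = x$run_values)
}

#' @describeIn calc_pm one-row summary (pm, p_half, convergence, points).
#' @export
glance.pm_estimate <- function(x, ...) {
  tibble::tibble(pm = x$pm, p_half = x$p_half,
                 pm_sd = if (length(x$run_values) > 1) stats::sd(x$run_values) else NA_real_,
                 runs = length(x$run_values),
                 n_points = nrow(x$curve),
                 converged = x$converged, boundary = x$boundary)
}

#' @describeIn calc_pm producibility-curve plot: sampled points (colour =
#'   run) with the PM marked at `P_in = 1 - PM`.
#' @param object a `pm_estimate`.
#' @export
autoplot.pm_estimate <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$p_in, y = .data$p_out,
                                    colour = factor(.data$run))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$p_half, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey50") +
    ggplot2::labs(x = expression(P["in"]), y = expression(P["out"]),
                  colour = "run",
                  title = sprintf("PM = %.3f (target %s)", object$pm,
                                  paste(object$target, collapse = "+"))) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  p
}

#' @describeIn mantel tidy one-row summary of a Mantel result.
#' @param x a `mantel_result`.
#' @param ... unused.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n_perm = x$n_perm,
                 n_stronger = x$n_stronger, method = x$method,
                 triangle = x$triangle,
                 partial = !is.na(x$partial))
}

#' @describeIn mantel alias of `tidy()` for a single-statistic object.
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x, ...)

#' @describeIn perturbation_study accuracy-versus-removal plot in the style
#'   of the robustness experiment: mean quantitative accuracy per level for
#'   FBA (minimal and complete medium) and the PM, with standard-error
#'   ribbons.
#' @param object a `perturbation_study` result.
#' @param ... unused.
#' @export
autoplot.perturbation_study <- function(object, ...) {
  s <- summarize_perturbation(object)
  long <- dplyr::bind_rows(
    tibble::tibble(level = s$level, metric = "FBA (minimal medium)",
                   mean = s$fba_minimal_mean, se = s$fba_minimal_se),
    tibble::tibble(level = s$level, metric = "FBA (complete medium)",
                   mean = s$fba_complete_mean, se = s$fba_complete_se),
    tibble::tibble(level = s$level, metric = "PM",
                   mean = s$pm_mean, se = s$pm_se))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$mean,
                                     colour = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reactions removed", y = "quantitative accuracy") +
    ggplot2::theme_minimal()
}
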