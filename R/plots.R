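#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_line
#'   labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Stimulus-response plot for a regression fit
#'
#' Scatter of responses against targets with the fitted regression line and
#' the identity (veridical) line for reference.
#'
#' @param object An `sr_fit` from [fit_stimulus_response()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sr_fit <- function(object, ...) {
  d <- tibble(target = object$model$model$targets,
              response = object$model$model$responses)
  ggplot(d, aes(x = .data$target, y = .data$response)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_abline(slope = object$gain, intercept = object$bias,
                colour = "firebrick") +
    labs(x = "target (deg)", y = "response (deg)",
         title = sprintf("gain = %.2f, sigma_res = %.2f deg",
                         object$gain, object$sigma_res)) +
    theme_minimal()
}

#' Gain-variance plot for a fitted decision model
#'
#' Observed gain against residual SD with the fitted model curve overlaid —
#' the standard way to display the accuracy-precision trade-off.
#'
#' @param object A `prior_fit` from [fit_prior_width()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.prior_fit <- function(object, ...) {
  curve_g <- seq(0, 1, length.out = 201)
  curve <- tibble(gain = curve_g,
                  sigma = scheme_sigma_curve(curve_g, object$sigma_p,
                                             object$scheme))
  ggplot(object$points, aes(x = .data$sigma_res, y = .data$gain)) +
    geom_point() +
    geom_line(data = curve, aes(x = .data$sigma, y = .data$gain),
              colour = "steelblue") +
    labs(x = "residual SD (deg)", y = "gain",
         title = sprintf("%s model: sigma_p = %.1f deg, r2 = %.2f",
                         object$scheme, object$sigma_p, object$r2)) +
    theme_minimal()
}

#' Gain-variance plot of a noise sweep
#'
#' Plots the (residual SD, gain) trace of each decision scheme from a
#' [noise_sweep()] table, optionally with the closed-form curves at a given
#' prior width.
#'
#' @param sweep A tibble from [noise_sweep()].
#' @param sigma_p Prior SD for overlaying the closed-form curves; `NULL`
#'   to omit.
#' @return A ggplot object.
#' @export
plot_gain_variance <- function(sweep, sigma_p = 11.5) {
  p <- ggplot(sweep, aes(x = .data$sigma_res, y = .data$gain,
                         colour = .data$scheme)) +
    geom_point(size = 0.8) +
    labs(x = "residual SD (deg)", y = "gain", colour = "scheme") +
    theme_minimal()
  if (!is.null(sigma_p)) {
    g <- seq(0, 1, length.out = 201)
    curves <- purrr::map_dfr(c("MAP", "AS", "PM"), function(sc) {
      tibble(scheme = sc, gain = g,
             sigma = scheme_sigma_curve(g, sigma_p, sc))
    })
    p <- p + geom_line(data = curves,
                       aes(x = .data$sigma, y = .data$gain,
                           colour = .data$scheme))
  }
  p
}
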