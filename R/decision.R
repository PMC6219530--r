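#' Decision-rule configuration
#'
#' Bundles the response-selection scheme and its parameters. Schemes:
#' * `"MLE"` — respond at the likelihood peak (flat-prior limit).
#' * `"MAP"` — respond at the posterior mode (= mean for Gaussians).
#' * `"PM"` — posterior matching: draw the response from the full posterior.
#' * `"AS"` — adaptive sampling: draw from a window of halfwidth
#'   \eqn{w_0 \hat\sigma} around the posterior peak, where \eqn{\hat\sigma}
#'   is the internal sensory-uncertainty estimate (see
#'   [estimate_sampling_halfwidth()]).
#' * `"MAP_BOX"` — MAP under a uniform box prior over the motor range: the
#'   likelihood peak clipped to the box.
#'
#' @param scheme Scheme tag, one of the above.
#' @param w0 Dimensionless sampling-width factor for `"AS"`; default 0.9.
#' @param box_halfwidth Halfwidth of the box prior in degrees (only
#'   `"MAP_BOX"`); default 35, the oculomotor range.
#' @param as_law How to draw within the adaptive-sampling window:
#'   `"truncated"` (posterior truncated to the window; converges to PM as the
#'   window grows and to MAP as it shrinks) or `"uniform"`.
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(scheme = c("MAP", "MLE", "PM", "AS", "MAP_BOX"),
                            w0 = 0.9, box_halfwidth = 35,
                            as_law = c("truncated", "uniform")) {
  scheme <- match.arg(scheme)
  as_law <- match.arg(as_law)
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0)
  stopifnot(is.numeric(box_halfwidth), length(box_halfwidth) == 1L,
            box_halfwidth > 0)
  structure(list(scheme = scheme, w0 = w0, box_halfwidth = box_halfwidth,
                 as_law = as_law),
            class = "decision_config")
}

#' @export
print.decision_config <- function(x, ...) {
  cat(sprintf("<decision_config> scheme = %s", x$scheme))
  if (x$scheme == "AS") cat(sprintf(", w0 = %g, law = %s", x$w0, x$as_law))
  if (x$scheme == "MAP_BOX") cat(sprintf(", box = +/-%g deg", x$box_halfwidth))
  cat("\n")
  invisible(x)
}

#' Draw noisy internal target estimates
#'
#' The internal estimate on trial *n* is the true target plus additive,
#' stimulus-independent Gaussian noise:
#' \eqn{\varepsilon^*_n = \varepsilon_T + \eta_n}, \eqn{\eta_n \sim N(0, \sigma_T^2)}.
#' Across trials the estimates scatter around the true location with SD
#' \eqn{\sigma_T}; their peak defines the trial's likelihood function.
#'
#' @param target True target coordinate(s), degrees.
#' @param sigma_t Sensory noise SD, degrees (`>= 0`; 0 gives the target back
#'   exactly).
#' @param n Number of draws; defaults to `length(target)` (targets recycle).
#' @return Numeric vector of internal estimates, degrees.
#' @export
sample_likelihood_peak <- function(target, sigma_t, n = length(target)) {
  stopifnot(is.numeric(target), is.numeric(sigma_t), length(sigma_t) == 1L,
            sigma_t >= 0)
  if (sigma_t == 0) return(rep_len(target, n))
  rep_len(target, n) + stats::rnorm(n, 0, sigma_t)
}

#' Maximum-likelihood response
#'
#' Responds at the likelihood peak: the identity on the internal estimate.
#' Equivalent to the MAP rule under a flat prior.
#'
#' @param eps_star Internal estimate(s), degrees.
#' @return `eps_star`, unchanged.
#' @export
decide_mle <- function(eps_star) {
  stopifnot(is.numeric(eps_star))
  eps_star
}

#' Maximum-a-posteriori response
#'
#' Responds at the posterior mode, which equals the posterior mean for
#' Gaussian beliefs. Deterministic given the posterior.
#'
#' @param posterior A [gaussian_belief()] posterior.
#' @return The posterior mean, degrees.
#' @export
decide_map <- function(posterior) {
  as_belief(posterior, "posterior")$mean
}

#' Posterior-matching response
#'
#' Draws the response from the full posterior: one Gaussian sample with the
#' posterior's mean and SD per trial. Across trials the response variance is
#' the variance of the posterior mean plus the posterior variance.
#'
#' @param posterior A [gaussian_belief()] posterior.
#' @param n Number of draws (default 1).
#' @return Numeric vector of responses, degrees.
#' @export
decide_pm <- function(posterior, n = 1) {
  posterior <- as_belief(posterior, "posterior")
  if (is.infinite(posterior$sd)) {
    stop("Cannot sample from a flat posterior.", call. = FALSE)
  }
  stats::rnorm(n, posterior$mean, posterior$sd)
}

#' Internal sensory-uncertainty estimate and sampling halfwidth
#'
#' The adaptive-sampling rule sets its window from an internal estimate of
#' the sensory noise computed from quantities the system plausibly has: the
#' widths of the posterior and the prior,
#' \deqn{\hat\sigma^2 = \frac{\sigma_{POST}^2}{1 - \sigma_{POST}^2/\sigma_P^2}.}
#' Algebraically \eqn{\hat\sigma = \sigma_T} exactly, so the halfwidth
#' \eqn{w_0 \hat\sigma} scales with the true sensory noise. As the posterior
#' width approaches the prior width (no sensory evidence) the estimate
#' diverges, signalling that the whole posterior should be sampled.
#'
#' @param posterior_sd Posterior SD, degrees (vectorised).
#' @param prior_sd Prior SD, degrees.
#' @param w0 Sampling-width factor (default 0.9).
#' @return Window halfwidth \eqn{w_0 \hat\sigma}, degrees; `Inf` where
#'   `posterior_sd >= prior_sd` (callers fall back to full-posterior
#'   sampling).
#' @export
estimate_sampling_halfwidth <- function(posterior_sd, prior_sd, w0 = 0.9) {
  stopifnot(is.numeric(posterior_sd), all(posterior_sd >= 0),
            is.numeric(prior_sd), prior_sd > 0, w0 > 0)
  ratio2 <- posterior_sd^2 / prior_sd^2
  ifelse(ratio2 >= 1, Inf, w0 * sqrt(posterior_sd^2 / (1 - ratio2)))
}

# inverse-CDF draws from N(mean, sd) truncated to [lo, hi]; vectorised
rtruncated_normal <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  stats::qnorm(u, mean, sd)
}

#' Adaptive-sampling response
#'
#' Draws the response from a restricted window
#' \eqn{[\mu_{POST} - h, \mu_{POST} + h]} around the posterior peak, with
#' halfwidth \eqn{h = w_0 \hat\sigma} from [estimate_sampling_halfwidth()].
#' With the default truncated-posterior law the rule interpolates between the
#' MAP response (window shrinks to a point at low sensory noise) and full
#' posterior matching (window engulfs the posterior at high noise). When the
#' posterior is no narrower than the prior — no sensory evidence — the
#' halfwidth diverges and the draw falls back to the full posterior, which is
#' then the prior itself.
#'
#' @param posterior A [gaussian_belief()] posterior.
#' @param prior A [gaussian_belief()] prior (supplies the prior width for the
#'   uncertainty estimate).
#' @param config A [decision_config()]; `w0` and `as_law` are used.
#' @param n Number of draws (default 1).
#' @return Numeric vector of responses, degrees.
#' @export
decide_as <- function(posterior, prior, config = decision_config("AS"),
                      n = 1) {
  posterior <- as_belief(posterior, "posterior")
  prior <- as_belief(prior, "prior")
  if (posterior$sd == 0) return(rep(posterior$mean, n))
  h <- estimate_sampling_halfwidth(posterior$sd, prior$sd, config$w0)
  if (is.infinite(h)) {
    return(decide_pm(posterior, n))
  }
  if (config$as_law == "uniform") {
    stats::runif(n, posterior$mean - h, posterior$mean + h)
  } else {
    rtruncated_normal(n, posterior$mean, posterior$sd,
                      posterior$mean - h, posterior$mean + h)
  }
}

#' MAP response under a uniform box prior
#'
#' With a box prior over the motor range (constant density inside
#' `[-box_halfwidth, +box_halfwidth]`, zero outside), the posterior is the
#' likelihood truncated to the box, whose mode is the likelihood peak clipped
#' to the box edges.
#'
#' @param eps_star Internal estimate(s), degrees.
#' @param box_halfwidth Box halfwidth, degrees (default 35).
#' @return Clipped response(s), degrees.
#' @examples
#' decide_map_box(c(-80, 20, 50), 35) # -35, 20, 35
#' @export
decide_map_box <- function(eps_star, box_halfwidth = 35) {
  stopifnot(is.numeric(eps_star), is.numeric(box_halfwidth),
            box_halfwidth > 0)
  pmin(pmax(eps_star, -box_halfwidth), box_halfwidth)
}
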