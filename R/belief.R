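#' Gaussian belief over one spatial coordinate
#'
#' A mean/SD pair representing a likelihood, prior, or posterior over a single
#' directional coordinate (azimuth or elevation), in degrees. An infinite SD is
#' the canonical encoding of a flat (uniform) belief, i.e. the
#' maximum-likelihood limit of an uninformative prior; arithmetic with it is
#' exact, not a large-number approximation.
#'
#' @param mean Belief mean in degrees; must be finite.
#' @param sd Belief standard deviation in degrees; strictly positive, `Inf`
#'   allowed.
#' @return An object of class `gaussian_belief`: a list with elements `mean`
#'   and `sd`.
#' @examples
#' gaussian_belief(-6.3, 8)
#' gaussian_belief(0, Inf) # flat belief
#' @export
gaussian_belief <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  stopifnot(is.numeric(sd), length(sd) == 1L, !is.na(sd))
  if (sd <= 0) {
    stop("`sd` must be strictly positive (Inf allowed for a flat belief).",
         call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> mean = %.4g deg, sd = %.4g deg\n",
              x$mean, x$sd))
  invisible(x)
}

#' @export
format.gaussian_belief <- function(x, ...) {
  sprintf("N(%.4g, %.4g)", x$mean, x$sd)
}

is_gaussian_belief <- function(x) inherits(x, "gaussian_belief")

as_belief <- function(x, what = "belief") {
  if (is_gaussian_belief(x)) return(x)
  if (is.numeric(x) && length(x) == 2L) return(gaussian_belief(x[1], x[2]))
  stop(sprintf("`%s` must be a gaussian_belief (or a length-2 mean/sd vector).",
               what), call. = FALSE)
}

#' Separable spatial prior for azimuth and elevation
#'
#' The spatial prior over sound directions is a product of two independent
#' zero-mean Gaussians, one per coordinate. Azimuth priors are at least as
#' wide as elevation priors: binaural difference cues make azimuth estimates
#' reliable over the whole frontal hemifield, whereas the elevation prior is
#' concentrated around the horizon.
#'
#' @param azimuth_sd Prior SD for azimuth, degrees (`Inf` for a flat azimuth
#'   prior, the maximum-likelihood limit).
#' @param elevation_sd Prior SD for elevation, degrees.
#' @return A list of class `spatial_prior` with `gaussian_belief` elements
#'   `azimuth` and `elevation`.
#' @examples
#' spatial_prior(azimuth_sd = Inf, elevation_sd = 11.5)
#' @export
spatial_prior <- function(azimuth_sd = Inf, elevation_sd = 11.5) {
  az <- gaussian_belief(0, azimuth_sd)
  el <- gaussian_belief(0, elevation_sd)
  if (az$sd < el$sd) {
    stop("The azimuth prior must be at least as wide as the elevation prior.",
         call. = FALSE)
  }
  structure(list(azimuth = az, elevation = el), class = "spatial_prior")
}

#' @export
print.spatial_prior <- function(x, ...) {
  cat("<spatial_prior>\n",
      "  azimuth:   ", format(x$azimuth), "\n",
      "  elevation: ", format(x$elevation), "\n", sep = "")
  invisible(x)
}

#' Combine a Gaussian likelihood with a Gaussian prior
#'
#' Conjugate Bayesian updating: the posterior over the coordinate is Gaussian
#' with precision equal to the sum of the likelihood and prior precisions, and
#' mean at the precision-weighted average of the two means. For a zero-mean
#' prior this is the classic shrinkage estimate
#' \deqn{\mu_{POST} = \frac{\varepsilon^*}{1 + \sigma_T^2/\sigma_P^2}, \qquad
#'       \sigma_{POST}^2 = \frac{\sigma_T^2}{1 + \sigma_T^2/\sigma_P^2}.}
#' A flat component (`sd = Inf`) leaves the other belief unchanged; this is
#' exact, so the maximum-likelihood limit needs no special casing downstream.
#'
#' @param likelihood A [gaussian_belief()]: the sensory likelihood, centred on
#'   the trial's noisy internal estimate with SD equal to the sensory noise.
#' @param prior A [gaussian_belief()]: the spatial prior for this coordinate.
#' @return A `gaussian_belief` holding the posterior mean and SD.
#' @examples
#' posterior_combine(gaussian_belief(-6.3, 8), gaussian_belief(0, 11.5))
#' @export
posterior_combine <- function(likelihood, prior) {
  likelihood <- as_belief(likelihood, "likelihood")
  prior <- as_belief(prior, "prior")
  if (is.infinite(likelihood$sd) && is.infinite(prior$sd)) {
    stop("Both beliefs are flat: the posterior is undefined.", call. = FALSE)
  }
  if (is.infinite(prior$sd)) return(likelihood)
  if (is.infinite(likelihood$sd)) return(prior)
  # precision-weighted combination, exact in the flat limits handled above
  w <- 1 / (1 + likelihood$sd^2 / prior$sd^2)
  mu <- w * likelihood$mean + (1 - w) * prior$mean
  gaussian_belief(mu, sqrt(likelihood$sd^2 * w))
}

check_sigma_p <- function(sigma_p) {
  stopifnot(is.numeric(sigma_p))
  if (any(sigma_p <= 0)) {
    stop("`sigma_p` must be strictly positive.", call. = FALSE)
  }
  invisible(sigma_p)
}

#' Closed-form response gain of the MAP decision rule
#'
#' Under the maximum-a-posteriori rule the mean response to a target at
#' \eqn{\varepsilon_T} is \eqn{G \cdot \varepsilon_T} with
#' \deqn{G_{MAP} = \frac{1}{1 + \sigma_T^2/\sigma_P^2},}
#' the shrinkage factor of the conjugate Gaussian posterior. The gain is 1
#' with no sensory noise and falls monotonically toward 0 as the noise grows.
#' Because all decision rules considered here share the posterior mean, this
#' is also the expected stimulus-response regression slope of the
#' posterior-matching and adaptive-sampling rules.
#'
#' @param sigma_t Sensory noise SD, degrees (vectorised, `>= 0`).
#' @param sigma_p Prior SD, degrees (vectorised, `> 0`; `Inf` gives gain 1).
#' @return Dimensionless gain in (0, 1].
#' @examples
#' map_gain(8, 11.5) # about 0.67
#' map_gain(8, Inf)  # the MLE limit: 1
#' @export
map_gain <- function(sigma_t, sigma_p) {
  stopifnot(is.numeric(sigma_t), all(sigma_t >= 0))
  check_sigma_p(sigma_p)
  out <- 1 / (1 + (sigma_t / sigma_p)^2)
  out[rep_len(is.infinite(sigma_p), length(out))] <- 1
  out
}

#' Gain-variance relation of the MAP rule
#'
#' The MAP rule's predicted response SD about the regression line, expressed
#' as a function of its own gain:
#' \deqn{\sigma_{MAP} = \sigma_P \sqrt{G (1 - G)}.}
#' The curve is a parabola in variance, zero at both G = 0 (prior-dominated,
#' the response never moves) and G = 1 (noise-free), with maximum
#' \eqn{\sigma_P / 2} at G = 0.5. The non-monotonicity — variability
#' *decreasing* again as the gain drops below 0.5 — is the rule's signature
#' prediction.
#'
#' @param gain Response gain in \[0, 1\] (vectorised).
#' @param sigma_p Prior SD, degrees.
#' @return Predicted residual SD, degrees.
#' @examples
#' map_sigma_curve(0.5, 11.5) # 5.75, the maximum
#' @export
map_sigma_curve <- function(gain, sigma_p) {
  stopifnot(is.numeric(gain))
  if (any(gain < 0 | gain > 1)) {
    stop("`gain` must lie in [0, 1].", call. = FALSE)
  }
  check_sigma_p(sigma_p)
  sigma_p * sqrt(gain * (1 - gain))
}

check_scheme_sigma <- function(sigma, sigma_p) {
  stopifnot(is.numeric(sigma), all(sigma >= 0))
  check_sigma_p(sigma_p)
  if (any(sigma > sigma_p)) {
    stop("Response SD above the prior SD implies a negative gain, which the model does not cover.",
         call. = FALSE)
  }
  invisible(sigma)
}

#' Gain-variance relation of the adaptive-sampling rule
#'
#' Under adaptive sampling the response SD equals the posterior SD, which
#' yields a linear relation in variance space with slope \eqn{-1/\sigma_P^2}:
#' \deqn{G_{AS} = 1 - \sigma_{AS}^2 / \sigma_P^2.}
#' The curve meets G = 0 exactly at \eqn{\sigma_{AS} = \sigma_P}: with no
#' usable sensory evidence the response scatter equals the prior width.
#'
#' @param sigma_as Response SD, degrees, in \[0, sigma_p\] (vectorised).
#' @param sigma_p Prior SD, degrees.
#' @return Dimensionless gain in \[0, 1\].
#' @export
as_gain_curve <- function(sigma_as, sigma_p) {
  check_scheme_sigma(sigma_as, sigma_p)
  1 - sigma_as^2 / sigma_p^2
}

#' Gain-variance relation of the posterior-matching rule
#'
#' Drawing the response from the full posterior on every trial gives total
#' response variance \eqn{G^2 \sigma_T^2 + \sigma_{POST}^2 = (1 - G^2)\sigma_P^2},
#' i.e.
#' \deqn{G_{PM} = \sqrt{1 - \sigma_{PM}^2 / \sigma_P^2}.}
#' The identity \eqn{\sigma_{PM}^2 = (1 - G^2)\sigma_P^2} is exact for
#' full-posterior sampling, not an approximation. Like the adaptive-sampling
#' curve it intersects G = 0 at the prior SD, but it predicts more
#' variability at intermediate gains.
#'
#' @inheritParams as_gain_curve
#' @param sigma_pm Response SD, degrees, in \[0, sigma_p\] (vectorised).
#' @return Dimensionless gain in \[0, 1\].
#' @export
pm_gain_curve <- function(sigma_pm, sigma_p) {
  check_scheme_sigma(sigma_pm, sigma_p)
  sqrt(1 - sigma_pm^2 / sigma_p^2)
}

#' Model-predicted residual SD at a given gain
#'
#' Inverse of the gain-variance relations: each decision rule predicts
#' residual variance \eqn{c(G) \, \sigma_P^2} with rule-specific
#' \eqn{c(G) = G(1-G)} (MAP), \eqn{1-G} (adaptive sampling), or
#' \eqn{1-G^2} (posterior matching). Used by the prior-width fitter, which is
#' linear in \eqn{\sigma_P^2} for every rule.
#'
#' @param gain Response gain in \[0, 1\] (vectorised).
#' @param sigma_p Prior SD, degrees.
#' @param scheme One of `"MAP"`, `"AS"`, `"PM"`.
#' @return Predicted residual SD, degrees.
#' @export
scheme_sigma_curve <- function(gain, sigma_p, scheme = c("MAP", "AS", "PM")) {
  scheme <- match.arg(scheme)
  check_sigma_p(sigma_p)
  sigma_p * sqrt(scheme_variance_factor(gain, scheme))
}

# c(G) such that predicted residual variance = c(G) * sigma_p^2
scheme_variance_factor <- function(gain, scheme) {
  stopifnot(is.numeric(gain))
  if (any(gain < 0 | gain > 1)) {
    stop("`gain` must lie in [0, 1].", call. = FALSE)
  }
  switch(scheme,
    MAP = gain * (1 - gain),
    AS  = 1 - gain,
    PM  = 1 - gain^2,
    stop(sprintf("Unknown scheme '%s'.", scheme), call. = FALSE)
  )
}
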