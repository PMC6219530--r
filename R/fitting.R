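#' Fit the prior width of a decision model to gain-variance points
#'
#' Each decision rule predicts residual variance
#' \eqn{\sigma^2 = c(G)\,\sigma_P^2} with a rule-specific factor
#' \eqn{c(G)}: \eqn{G(1-G)} for MAP, \eqn{1-G} for adaptive sampling,
#' \eqn{1-G^2} for posterior matching. The relation is linear in
#' \eqn{\sigma_P^2}, so the least-squares estimate in variance space is
#' closed-form:
#' \deqn{\hat\sigma_P^2 = \frac{\sum_i c_i \sigma_i^2}{\sum_i c_i^2}.}
#' Goodness of fit is reported on the SD scale (the scale on which
#' gain-variance data are plotted): \eqn{r^2 = 1 - SS_{res}/SS_{tot}} between
#' observed and model-predicted \eqn{\sigma}, together with their Pearson
#' correlation *r*.
#'
#' @param points A data frame of gain-variance observations, one row per
#'   subject-by-condition-by-component cell.
#' @param scheme Decision model to fit: `"MAP"`, `"AS"`, or `"PM"`.
#' @param gain,sigma_res Columns holding the gains and residual SDs
#'   (tidy-eval; defaults `gain`, `sigma_res`).
#' @param fit_space `"variance"` (default; the closed-form estimator above)
#'   or `"sigma"` (least squares on the SD scale, for sensitivity checks:
#'   \eqn{\hat\sigma_P = \sum_i \sigma_i \sqrt{c_i} / \sum_i c_i}).
#' @return An object of class `prior_fit` with elements `scheme`, `sigma_p`,
#'   `r2`, `r`, `n`, and a `points` tibble carrying the per-point
#'   predictions. [tidy()] returns the per-point table, [glance()] the
#'   one-row fit summary.
#' @examples
#' pts <- tibble::tibble(gain = c(0.2, 0.5, 0.8),
#'                       sigma_res = scheme_sigma_curve(c(0.2, 0.5, 0.8),
#'                                                     12.5, "AS"))
#' glance(fit_prior_width(pts, "AS")) # recovers sigma_p = 12.5, r2 = 1
#' @export
fit_prior_width <- function(points, scheme = c("MAP", "AS", "PM"),
                            gain = gain, sigma_res = sigma_res,
                            fit_space = c("variance", "sigma")) {
  scheme <- match.arg(scheme)
  fit_space <- match.arg(fit_space)
  stopifnot(is.data.frame(points))
  g <- dplyr::pull(points, {{ gain }})
  s <- dplyr::pull(points, {{ sigma_res }})
  if (length(g) < 2) stop("Need at least 2 points.", call. = FALSE)
  if (any(g < 0 | g > 1)) stop("Gains must lie in [0, 1].", call. = FALSE)
  if (any(s < 0)) stop("Residual SDs must be non-negative.", call. = FALSE)
  cg <- scheme_variance_factor(g, scheme)
  if (all(cg == 0)) {
    stop("All gains sit at degenerate values for this model; the prior width is unidentifiable.",
         call. = FALSE)
  }
  sigma_p <- if (fit_space == "variance") {
    sqrt(sum(cg * s^2) / sum(cg^2))
  } else {
    sum(s * sqrt(cg)) / sum(cg)
  }
  pred <- sigma_p * sqrt(cg)
  ss_res <- sum((s - pred)^2)
  ss_tot <- sum((s - mean(s))^2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, -Inf) else 1 - ss_res / ss_tot
  r <- if (stats::sd(pred) == 0 || stats::sd(s) == 0) NA_real_ else
    stats::cor(s, pred)
  structure(
    list(scheme = scheme, sigma_p = sigma_p, r2 = r2, r = r, n = length(g),
         fit_space = fit_space,
         points = tibble(gain = g, sigma_res = s, predicted = pred)),
    class = "prior_fit"
  )
}

#' @export
print.prior_fit <- function(x, ...) {
  cat(sprintf(
    "<prior_fit> %s model, n = %d points\n  sigma_p = %.2f deg, r2 = %.3f, r = %.3f\n",
    x$scheme, x$n, x$sigma_p, x$r2, x$r))
  invisible(x)
}

#' @export
tidy.prior_fit <- function(x, ...) x$points

#' @export
glance.prior_fit <- function(x, ...) {
  tibble(scheme = x$scheme, sigma_p = x$sigma_p, r.squared = x$r2,
         r = x$r, n = x$n)
}

#' Constant-gain (MLE) summary of gain-variance points
#'
#' The maximum-likelihood model predicts a gain independent of residual
#' variability; its summary is simply the mean and sample SD (divisor
#' *n* − 1) of the observed gains.
#'
#' @inheritParams fit_prior_width
#' @return A one-row tibble: `mean_gain`, `sd_gain`, `n`.
#' @export
mle_constant_gain <- function(points, gain = gain) {
  g <- dplyr::pull(points, {{ gain }})
  if (length(g) < 2) stop("Need at least 2 points.", call. = FALSE)
  tibble(mean_gain = mean(g), sd_gain = stats::sd(g), n = length(g))
}

#' Fit and compare all decision models on one point set
#'
#' Convenience wrapper: fits the prior width for each of the MAP, adaptive
#' sampling and posterior-matching models on the same gain-variance points
#' and stacks the [glance()] summaries, appending the constant-gain MLE row
#' (for which no prior width exists).
#'
#' @inheritParams fit_prior_width
#' @param schemes Models to fit (default all three curve models).
#' @return A tibble with one row per model: `scheme`, `sigma_p`,
#'   `r.squared`, `r`, `n` (the MLE row reports the mean gain in a
#'   `mean_gain` column and `NA` for curve statistics).
#' @export
compare_decision_models <- function(points, schemes = c("MAP", "AS", "PM"),
                                    gain = gain, sigma_res = sigma_res,
                                    fit_space = c("variance", "sigma")) {
  fit_space <- match.arg(fit_space)
  fits <- purrr::map_dfr(schemes, function(sc) {
    glance(fit_prior_width(points, sc, {{ gain }}, {{ sigma_res }},
                           fit_space = fit_space))
  })
  mle <- mle_constant_gain(points, {{ gain }})
  dplyr::bind_rows(
    dplyr::mutate(fits, mean_gain = NA_real_),
    tibble(scheme = "MLE", sigma_p = NA_real_, r.squared = NA_real_,
           r = NA_real_, n = mle$n, mean_gain = mle$mean_gain)
  )
}

#' Compare two model correlations
#'
#' Tests whether one model's correlation with the data is larger than
#' another's. The default is the independent-samples Fisher r-to-z test,
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'              {\sqrt{2/(n-3)}},}
#' with a two-sided normal p-value. Because two models fitted to the same
#' points share data, a dependent-correlation variant (Steiger's Z for two
#' correlations sharing a variable) is available via `method = "steiger"`;
#' it additionally needs `r12`, the correlation between the two models'
#' predictions.
#'
#' @param r1,r2 The two correlations, each in (-1, 1).
#' @param n Number of points underlying each correlation (`n >= 4`).
#' @param method `"fisher"` (independent, default) or `"steiger"`
#'   (dependent, sharing a variable).
#' @param r12 Correlation between the two predictors (Steiger only).
#' @return A one-row tibble: `z`, `p.value`, `method`.
#' @examples
#' compare_model_correlations(0.94, 0.83, 30)
#' @export
compare_model_correlations <- function(r1, r2, n,
                                       method = c("fisher", "steiger"),
                                       r12 = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(r1), is.numeric(r2), abs(r1) < 1, abs(r2) < 1,
            is.numeric(n), n >= 4)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  if (method == "fisher") {
    z <- (z1 - z2) / sqrt(2 / (n - 3))
  } else {
    if (is.null(r12)) {
      stop("Steiger's test needs `r12`, the correlation between the two predictors.",
           call. = FALSE)
    }
    stopifnot(abs(r12) <= 1)
    rbar2 <- (r1^2 + r2^2) / 2
    f <- min((1 - r12) / (2 * (1 - rbar2)), 1)
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  tibble(z = z, p.value = 2 * stats::pnorm(-abs(z)), method = method)
}
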