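#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Stimulus-response regression for one response set
#'
#' Fits the linear stimulus-response relation \eqn{R = g T + b} by least
#' squares and summarises accuracy and precision: the gain *g* (slope; 1 is
#' veridical), the bias *b* (offset, degrees), and the residual SD
#' \eqn{\sigma_{res} = \sqrt{\langle (R - \hat R)^2 \rangle}} — the plain
#' root-mean-square of the residuals (divisor *n*, not *n* − 2, matching the
#' variability definition used throughout; at n = 1000 the two differ by
#' about 0.1%).
#'
#' @param data A data frame of trials.
#' @param target,response Columns holding the stimulus and response
#'   coordinates in degrees (tidy-eval; defaults `target`, `response`).
#' @return An object of class `sr_fit`: a list with `gain`, `bias`,
#'   `sigma_res`, `n`, `r2` and the underlying `lm` fit. Use [tidy()] /
#'   [glance()] for tibble output, [autoplot()][autoplot.sr_fit] for the
#'   stimulus-response plot.
#' @examples
#' sim <- simulate_trials(500, sigma_t = 8, scheme = "MAP", seed = 42)
#' glance(fit_stimulus_response(sim))
#' @export
fit_stimulus_response <- function(data, target = target, response = response) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ target }})
  r <- dplyr::pull(data, {{ response }})
  fit_linear(t, r)
}

#' @rdname fit_stimulus_response
#' @param targets,responses Numeric vectors of equal length (vector
#'   interface behind [fit_stimulus_response()]).
#' @export
fit_linear <- function(targets, responses) {
  stopifnot(is.numeric(targets), is.numeric(responses),
            length(targets) == length(responses))
  n <- length(targets)
  if (n < 2) stop("Need at least 2 trials to fit a line.", call. = FALSE)
  if (stats::sd(targets) == 0) {
    stop("All targets identical: the regression is rank-deficient.",
         call. = FALSE)
  }
  fit <- stats::lm(responses ~ targets)
  res <- stats::residuals(fit)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(
    list(gain = unname(stats::coef(fit)[2]),
         bias = unname(stats::coef(fit)[1]),
         sigma_res = sqrt(mean(res^2)),
         n = n,
         r2 = if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot,
         model = fit),
    class = "sr_fit"
  )
}

#' @export
print.sr_fit <- function(x, ...) {
  cat(sprintf(
    "<sr_fit> n = %d trials\n  gain = %.3f, bias = %.2f deg, sigma_res = %.2f deg\n",
    x$n, x$gain, x$bias, x$sigma_res))
  invisible(x)
}

#' @export
tidy.sr_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("bias", "gain"),
         estimate = c(x$bias, x$gain),
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.sr_fit <- function(x, ...) {
  tibble(gain = x$gain, bias = x$bias, sigma_res = x$sigma_res,
         r.squared = x$r2, n = x$n)
}

#' Per-group stimulus-response regressions
#'
#' Maps [fit_stimulus_response()] over groups of a trial table (for example
#' subject by condition by component) and returns one row of regression
#' summaries per group — the gain-variance points that the model comparison
#' consumes.
#'
#' @param data A data frame of trials.
#' @param ... Grouping columns (tidy-eval), e.g. `subject, condition,
#'   component`.
#' @inheritParams fit_stimulus_response
#' @return A tibble with the grouping columns plus `gain`, `bias`,
#'   `sigma_res`, `n`.
#' @examples
#' study <- generate_snr_experiment(n_subjects = 2, trials_per_condition = 24,
#'                                  seed = 7)
#' trials <- tidyr::pivot_longer(study,
#'   cols = c(target_az, target_el, resp_az, resp_el),
#'   names_to = c(".value", "component"), names_sep = "_")
#' regress_components(trials, subject, condition, component,
#'                    target = target, response = resp)
#' @export
regress_components <- function(data, ..., target = target,
                               response = response) {
  data |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_stimulus_response(d, {{ target }}, {{ response }})) |>
        dplyr::select(-"r.squared")
    }) |>
    dplyr::ungroup()
}

#' Flag outlying regression gains
#'
#' Group-level exclusion rule: a regression result whose gain deviates by
#' more than `k` standard deviations from the mean gain of the set is flagged
#' for exclusion. The mean and SD are computed over the full input set and
#' the rule is applied in a single pass (no re-iteration after removal).
#'
#' @param results A data frame of regression summaries (one row per fit).
#' @param gain Column holding the gains (tidy-eval; default `gain`).
#' @param k Exclusion threshold in SD units (default 3).
#' @return The input tibble with a logical `excluded` column appended. With
#'   fewer than 3 rows no exclusion is attempted (all `FALSE`, with a
#'   warning).
#' @examples
#' pts <- tibble::tibble(gain = c(rep(0.9, 7), 0.2))
#' exclude_outlier_gains(pts)
#' @export
exclude_outlier_gains <- function(results, gain = gain, k = 3) {
  stopifnot(is.data.frame(results), k > 0)
  g <- dplyr::pull(results, {{ gain }})
  results <- as_tibble(results)
  if (length(g) < 3) {
    warning("Fewer than 3 regression results: outlier exclusion skipped.",
            call. = FALSE)
    return(dplyr::mutate(results, excluded = FALSE))
  }
  s <- stats::sd(g)
  flag <- if (s == 0) rep(FALSE, length(g)) else abs(g - mean(g)) > k * s
  dplyr::mutate(results, excluded = flag)
}
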