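#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# vectorised response selection for a block with common sigma_t and prior
apply_scheme <- function(eps_star, sigma_t, prior, config) {
  n <- length(eps_star)
  if (config$scheme == "MLE") return(decide_mle(eps_star))
  if (config$scheme == "MAP_BOX") {
    return(decide_map_box(eps_star, config$box_halfwidth))
  }
  if (sigma_t == 0) return(eps_star) # point-mass posterior at the target
  w <- map_gain(sigma_t, prior$sd)
  mu_post <- w * eps_star + (1 - w) * prior$mean
  sd_post <- sqrt(w) * sigma_t
  switch(config$scheme,
    MAP = mu_post,
    PM  = stats::rnorm(n, mu_post, sd_post),
    AS  = {
      h <- estimate_sampling_halfwidth(sd_post, prior$sd, config$w0)
      if (is.infinite(h)) {
        stats::rnorm(n, mu_post, sd_post)
      } else if (config$as_law == "uniform") {
        stats::runif(n, mu_post - h, mu_post + h)
      } else {
        rtruncated_normal(n, mu_post, sd_post, mu_post - h, mu_post + h)
      }
    },
    stop(sprintf("Unknown scheme '%s'.", config$scheme), call. = FALSE)
  )
}

#' Simulate a block of localisation trials
#'
#' Runs the full generative model for one noise condition: targets drawn
#' uniformly over the target range, internal estimates perturbed by additive
#' Gaussian sensory noise, the conjugate posterior formed against the prior,
#' and the configured decision rule applied per trial.
#'
#' @param n_trials Number of trials (default 1000).
#' @param target_range Length-2 numeric: target interval in degrees
#'   (default `c(-35, 35)`).
#' @param sigma_t Sensory noise SD, degrees.
#' @param prior A [gaussian_belief()] prior for the simulated coordinate
#'   (default zero-mean, SD 11.5 deg — the elevation prior).
#' @param scheme Decision scheme tag or a full [decision_config()].
#' @param w0,as_law,box_halfwidth Passed to [decision_config()] when `scheme`
#'   is a tag.
#' @param seed Optional integer; when given, the block is reproducible and
#'   the session RNG state is restored afterwards.
#' @return A tibble with one row per trial: `trial`, `target`, `eps_star`
#'   (the internal estimate), `response` (degrees).
#' @examples
#' sim <- simulate_trials(1000, sigma_t = 8, scheme = "MAP", seed = 1)
#' fit_stimulus_response(sim)
#' @export
simulate_trials <- function(n_trials = 1000, target_range = c(-35, 35),
                            sigma_t = 8,
                            prior = gaussian_belief(0, 11.5),
                            scheme = "MAP", w0 = 0.9,
                            as_law = c("truncated", "uniform"),
                            box_halfwidth = 35, seed = NULL) {
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1)
  stopifnot(is.numeric(target_range), length(target_range) == 2L,
            target_range[1] < target_range[2])
  stopifnot(is.numeric(sigma_t), length(sigma_t) == 1L, sigma_t >= 0)
  prior <- as_belief(prior, "prior")
  config <- if (inherits(scheme, "decision_config")) scheme else {
    decision_config(scheme, w0 = w0, box_halfwidth = box_halfwidth,
                    as_law = match.arg(as_law))
  }
  with_optional_seed(seed, {
    targets <- stats::runif(n_trials, target_range[1], target_range[2])
    eps_star <- sample_likelihood_peak(targets, sigma_t)
    responses <- apply_scheme(eps_star, sigma_t, prior, config)
    tibble(trial = seq_len(n_trials), target = targets,
           eps_star = eps_star, response = responses)
  })
}

#' Sweep sensory noise across decision schemes
#'
#' Repeats [simulate_trials()] plus stimulus-response regression over a grid
#' of sensory noise levels for each scheme, producing one (gain, residual SD)
#' point per scheme and noise condition. The defaults reproduce the standard
#' model sweep: \eqn{\sigma_T} from 1 to 60 deg in 0.5-deg steps (119
#' conditions), 1000 trials per condition, targets uniform on
#' \eqn{[-90, +90]} deg, prior SD 11.5 deg.
#'
#' @param sigma_grid Numeric vector of sensory noise SDs, degrees.
#' @param schemes Character vector of scheme tags.
#' @param n_per_condition Trials per scheme-by-noise cell (default 1000).
#' @param target_range Target interval, degrees (default `c(-90, 90)`).
#' @param prior A [gaussian_belief()] prior.
#' @param w0 Adaptive-sampling width factor.
#' @param as_law Within-window sampling law for `"AS"`.
#' @param seed Optional integer seed for the whole sweep.
#' @return A tibble with columns `scheme`, `sigma_t`, `gain`, `bias`,
#'   `sigma_res`, `n`.
#' @examples
#' sweep <- noise_sweep(sigma_grid = c(4, 8, 16), schemes = "MAP",
#'                      n_per_condition = 500, seed = 1)
#' @export
noise_sweep <- function(sigma_grid = seq(1, 60, by = 0.5),
                        schemes = c("MAP", "AS", "PM"),
                        n_per_condition = 1000,
                        target_range = c(-90, 90),
                        prior = gaussian_belief(0, 11.5),
                        w0 = 0.9, as_law = c("truncated", "uniform"),
                        seed = NULL) {
  stopifnot(length(sigma_grid) >= 1, n_per_condition >= 2)
  as_law <- match.arg(as_law)
  prior <- as_belief(prior, "prior")
  grid <- tidyr::expand_grid(scheme = schemes, sigma_t = sigma_grid)
  with_optional_seed(seed, {
    purrr::pmap_dfr(grid, function(scheme, sigma_t) {
      sim <- simulate_trials(n_per_condition, target_range, sigma_t,
                             prior = prior, scheme = scheme, w0 = w0,
                             as_law = as_law)
      fit <- fit_stimulus_response(sim)
      tibble(scheme = scheme, sigma_t = sigma_t, gain = fit$gain,
             bias = fit$bias, sigma_res = fit$sigma_res, n = fit$n)
    })
  })
}
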