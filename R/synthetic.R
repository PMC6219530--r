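#' Map signal-to-noise ratio to sensory noise SD
#'
#' Fixture mapping used by the synthetic-study generator: a four-parameter
#' logistic in dB, monotonically non-increasing in SNR, with floor
#' `sigma_min` (noise at very high SNR), ceiling `sigma_max` (noise when the
#' target drowns in the background), midpoint and slope in dB. This is
#' plumbing for generating study-shaped data, not an empirical law: the
#' defaults are chosen so that, with an elevation prior of 11.5 deg, the
#' implied MAP gain falls from about 0.87 at +30 dB to about 0.33 at -21 dB.
#'
#' @param snr_db Signal-to-noise ratio(s), dB (vectorised).
#' @param sigma_min,sigma_max Floor and ceiling of the noise SD, degrees.
#' @param midpoint SNR at the logistic midpoint, dB.
#' @param slope Logistic width, dB (> 0).
#' @return Sensory noise SD(s), degrees.
#' @examples
#' snr_to_sigma(c(30, -6, -12, -18, -21))
#' @export
snr_to_sigma <- function(snr_db, sigma_min = 4.5, sigma_max = 18,
                         midpoint = -14, slope = 3.5) {
  stopifnot(is.numeric(snr_db))
  if (!(sigma_max > sigma_min && sigma_min >= 0 && slope > 0)) {
    stop("Need sigma_max > sigma_min >= 0 and slope > 0 for a monotone SNR map.",
         call. = FALSE)
  }
  sigma_min + (sigma_max - sigma_min) / (1 + exp((snr_db - midpoint) / slope))
}

#' Target grid of the SNR localisation paradigm
#'
#' The fixed target locations of the paradigm: 12 polar directions (every
#' 30 deg) crossed with eccentricities of 14, 20 and 27 deg, all inside the
#' +/- 35 deg stimulus range.
#'
#' @return A 36-row tibble with `target_az`, `target_el` in degrees.
#' @export
snr_target_grid <- function() {
  grid <- tidyr::expand_grid(direction = (0:11) * 30,
                             eccentricity = c(14, 20, 27))
  tibble(
    target_az = grid$eccentricity * cospi(grid$direction / 180),
    target_el = grid$eccentricity * sinpi(grid$direction / 180)
  )
}

#' Random targets over the frontal hemifield
#'
#' Draws target locations for the low-pass paradigm: azimuth uniform on
#' \[-90, +90\] deg, elevation uniform on \[-55, +85\] deg, rejecting draws
#' that violate the double-pole coordinate constraint
#' \eqn{|\alpha| + |\varepsilon| \le 90} deg (points outside it do not exist
#' in the frontal hemifield).
#'
#' @param n Number of targets.
#' @return An `n`-row tibble with `target_az`, `target_el` in degrees.
#' @export
lowpass_target_grid <- function(n) {
  stopifnot(is.numeric(n), n >= 0)
  out <- tibble(target_az = numeric(0), target_el = numeric(0))
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    az <- stats::runif(m, -90, 90)
    el <- stats::runif(m, -55, 85)
    keep <- abs(az) + abs(el) <= 90
    out <- dplyr::bind_rows(out, tibble(target_az = az[keep],
                                        target_el = el[keep]))
  }
  out[seq_len(n), ]
}

# azimuth responder shared by both synthetic experiments: a high-gain
# MLE-like channel with a fixed ~10% undershoot on the noisy estimate
azimuth_response <- function(target_az, sigma_az, azimuth_gain = 0.9) {
  azimuth_gain * sample_likelihood_peak(target_az, sigma_az)
}

#' Generate a synthetic SNR localisation study
#'
#' Emulates the shape and statistical structure of an eye-saccade
#' localisation experiment in acoustic background noise: `n_subjects`
#' listeners localise broadband buzzers at the 24-location grid
#' ([snr_target_grid()]) under a set of SNR conditions. Elevation responses
#' follow the configured Bayesian decision rule (default adaptive sampling
#' with a zero-mean prior of SD `sigma_p_elevation`), with sensory noise set
#' per condition by [snr_to_sigma()]. Azimuth responses are MLE-like with a
#' fixed gain of `azimuth_gain` and milder noise, emulating the robustness
#' of binaural difference cues. Between-subject heterogeneity enters as
#' Gaussian jitter on the elevation prior width and on the SNR-map midpoint.
#'
#' @param n_subjects Number of synthetic subjects (default 5).
#' @param snr_levels SNR conditions in dB (default `c(30, -6, -12, -18, -21)`,
#'   +30 being the no-background control).
#' @param trials_per_condition Trials per subject and SNR (default 72, three
#'   cycles of the 24-location grid; 0 gives an empty table).
#' @param sigma_p_elevation Elevation prior SD, degrees (default 11.5).
#' @param elevation_scheme Decision rule for elevation, a tag or
#'   [decision_config()]. The default is adaptive sampling with the
#'   uniform-within-window law: over this study's noise range (sensory noise
#'   well below 2 prior widths) the uniform window with `w0 = 0.9`
#'   reproduces the adaptive-sampling statistics (response SD tracking the
#'   posterior SD) most closely, which is the behaviour the generator is
#'   meant to emulate.
#' @param azimuth_gain Fixed azimuth response gain (default 0.9).
#' @param sigma_map_params Named list overriding [snr_to_sigma()] parameters.
#' @param subject_sd_jitter SD of between-subject jitter on the elevation
#'   prior width, degrees (default 0.6).
#' @param subject_midpoint_jitter SD of between-subject jitter on the
#'   SNR-map midpoint, dB (default 1.5).
#' @param seed Optional integer seed.
#' @return A tibble with columns `experiment`, `subject`, `condition` (dB,
#'   numeric), `trial`, `target_az`, `target_el`, `resp_az`, `resp_el`.
#' @examples
#' study <- generate_snr_experiment(n_subjects = 2,
#'                                  trials_per_condition = 24, seed = 1)
#' dplyr::count(study, subject, condition)
#' @export
generate_snr_experiment <- function(n_subjects = 5,
                                    snr_levels = c(30, -6, -12, -18, -21),
                                    trials_per_condition = 72,
                                    sigma_p_elevation = 11.5,
                                    elevation_scheme = decision_config(
                                      "AS", as_law = "uniform"),
                                    azimuth_gain = 0.9,
                                    sigma_map_params = list(),
                                    subject_sd_jitter = 0.6,
                                    subject_midpoint_jitter = 1.5,
                                    seed = NULL) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 0)
  config <- if (inherits(elevation_scheme, "decision_config")) {
    elevation_scheme
  } else {
    decision_config(elevation_scheme)
  }
  smp <- utils::modifyList(
    list(sigma_min = 4.5, sigma_max = 18, midpoint = -14, slope = 3.5),
    sigma_map_params
  )
  empty <- tibble(experiment = character(0), subject = character(0),
                  condition = numeric(0), trial = integer(0),
                  target_az = numeric(0), target_el = numeric(0),
                  resp_az = numeric(0), resp_el = numeric(0))
  if (trials_per_condition == 0) return(empty)
  grid <- snr_target_grid()
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      sigma_p_s <- max(stats::rnorm(1, sigma_p_elevation, subject_sd_jitter),
                       1)
      prior_s <- gaussian_belief(0, sigma_p_s)
      midpoint_s <- stats::rnorm(1, smp$midpoint, subject_midpoint_jitter)
      purrr::map_dfr(snr_levels, function(snr) {
        sigma_el <- snr_to_sigma(snr, smp$sigma_min, smp$sigma_max,
                                 midpoint_s, smp$slope)
        sigma_az <- pmax(2, 0.35 * sigma_el)
        idx <- rep_len(sample.int(nrow(grid)), trials_per_condition)
        tg <- grid[idx, ]
        eps_el <- sample_likelihood_peak(tg$target_el, sigma_el)
        tibble(experiment = "SNR",
               subject = sprintf("S%d", s),
               condition = snr,
               trial = seq_len(trials_per_condition),
               target_az = tg$target_az,
               target_el = tg$target_el,
               resp_az = azimuth_response(tg$target_az, sigma_az,
                                          azimuth_gain),
               resp_el = apply_scheme(eps_el, sigma_el, prior_s, config))
      })
    })
  })
}

#' Generate a synthetic low-pass localisation study
#'
#' Emulates head-pointing localisation of low-pass filtered noises over the
#' frontal hemifield. Low-pass sounds carry intact binaural azimuth cues but
#' no spectral elevation cues, so the elevation channel receives no sensory
#' evidence: elevation responses are draws from the spatial prior (mean 0,
#' SD about the prior width), while azimuth responses stay high-gain.
#' Targets satisfy the double-pole constraint
#' \eqn{|\alpha| + |\varepsilon| \le 90} deg.
#'
#' @param n_subjects Number of synthetic subjects (default 7).
#' @param trials_per_subject Trials per subject (default 105, so that 7
#'   subjects pool to about 730 responses).
#' @param sigma_p_elevation Elevation prior SD, degrees (default 11.5).
#' @param azimuth_gain Fixed azimuth response gain (default 0.9).
#' @param sigma_az Azimuth sensory noise SD for head pointing, degrees
#'   (default 6).
#' @param subject_sd_jitter Between-subject jitter on the prior width,
#'   degrees (default 0.6).
#' @param seed Optional integer seed.
#' @return A tibble with the same schema as [generate_snr_experiment()],
#'   with `experiment = "LOWPASS"` and `condition = NA`.
#' @export
generate_lowpass_experiment <- function(n_subjects = 7,
                                        trials_per_subject = 105,
                                        sigma_p_elevation = 11.5,
                                        azimuth_gain = 0.9,
                                        sigma_az = 6,
                                        subject_sd_jitter = 0.6,
                                        seed = NULL) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 0)
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      sigma_p_s <- max(stats::rnorm(1, sigma_p_elevation, subject_sd_jitter),
                       1)
      tg <- lowpass_target_grid(trials_per_subject)
      tibble(experiment = "LOWPASS",
             subject = sprintf("S%d", n_subjects + s),
             condition = NA_real_,
             trial = seq_len(trials_per_subject),
             target_az = tg$target_az,
             target_el = tg$target_el,
             resp_az = azimuth_response(tg$target_az, sigma_az, azimuth_gain),
             # no spectral cues: the posterior is the prior itself
             resp_el = stats::rnorm(trials_per_subject, 0, sigma_p_s))
    })
  })
}

#' Reshape a study table to one row per trial and component
#'
#' Pivots the wide per-trial schema (`target_az`/`target_el`,
#' `resp_az`/`resp_el`) into a long table with a `component` column
#' (`"az"` / `"el"`) and `target` / `response` columns, ready for
#' [regress_components()].
#'
#' @param study A study tibble from [generate_snr_experiment()] or
#'   [generate_lowpass_experiment()].
#' @return A long tibble with columns `experiment`, `subject`, `condition`,
#'   `trial`, `component`, `target`, `response`.
#' @examples
#' study <- generate_lowpass_experiment(n_subjects = 2,
#'                                      trials_per_subject = 20, seed = 3)
#' study_to_trials(study) |>
#'   regress_components(subject, component)
#' @export
study_to_trials <- function(study) {
  stopifnot(all(c("target_az", "target_el", "resp_az", "resp_el") %in%
                  names(study)))
  study |>
    tidyr::pivot_longer(
      cols = c("target_az", "target_el", "resp_az", "resp_el"),
      names_to = c(".value", "component"),
      names_pattern = "(target|resp)_(az|el)"
    ) |>
    dplyr::rename(response = "resp")
}
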