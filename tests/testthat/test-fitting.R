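test_that("noiseless points on each model's curve are recovered exactly", {
  g <- c(0.15, 0.3, 0.5, 0.7, 0.9)
  for (scheme in c("MAP", "AS", "PM")) {
    for (sp in c(11.5, 12.5, 23.8)) {
      pts <- tibble::tibble(gain = g,
                            sigma_res = scheme_sigma_curve(g, sp, scheme))
      fit <- fit_prior_width(pts, scheme)
      expect_equal(fit$sigma_p, sp, tolerance = 1e-10)
      expect_equal(fit$r2, 1, tolerance = 1e-10)
      expect_equal(fit$r, 1, tolerance = 1e-10)
    }
  }
})

test_that("a repeated mid-gain MAP point inverts the parabola to the prior", {
  pts <- tibble::tibble(gain = c(0.5, 0.5), sigma_res = c(5.75, 5.75))
  expect_equal(fit_prior_width(pts, "MAP")$sigma_p, 11.5, tolerance = 1e-10)
})

test_that("the variance-space estimator matches its closed form", {
  withr::with_seed(61, {
    g <- runif(12, 0.05, 0.95)
    s <- scheme_sigma_curve(g, 11.5, "AS") * exp(rnorm(12, 0, 0.1))
    cg <- 1 - g
    expect_equal(fit_prior_width(tibble::tibble(gain = g, sigma_res = s),
                                 "AS")$sigma_p,
                 sqrt(sum(cg * s^2) / sum(cg^2)), tolerance = 1e-12)
    # sigma-space alternative: its own closed form
    expect_equal(fit_prior_width(tibble::tibble(gain = g, sigma_res = s),
                                 "AS", fit_space = "sigma")$sigma_p,
                 sum(s * sqrt(cg)) / sum(cg), tolerance = 1e-12)
  })
})

test_that("prior fitting rejects degenerate or invalid point sets", {
  expect_error(fit_prior_width(tibble::tibble(gain = 0.5, sigma_res = 5), "AS"),
               "at least 2")
  expect_error(fit_prior_width(tibble::tibble(gain = c(1.2, 0.5),
                                              sigma_res = c(1, 2)), "AS"))
  # all gains at values where the model predicts zero variance
  degen <- tibble::tibble(gain = c(0, 1, 1), sigma_res = c(1, 2, 3))
  expect_error(fit_prior_width(degen, "MAP"), "unidentifiable")
})

test_that("a PM noise sweep returns the generating prior width", {
  sw <- noise_sweep(sigma_grid = seq(2, 60, by = 2), schemes = "PM",
                    n_per_condition = 1000, target_range = c(-90, 90),
                    prior = gaussian_belief(0, 11.5), seed = 4)
  sw$gain <- pmin(pmax(sw$gain, 0), 1)
  fit <- fit_prior_width(sw, "PM")
  expect_lt(abs(fit$sigma_p - 11.5), 0.3)
  expect_gt(fit$r2, 0.95)
})

test_that("the generating model wins the cross-model comparison", {
  sw <- noise_sweep(sigma_grid = seq(2, 60, by = 2), schemes = "PM",
                    n_per_condition = 1000, target_range = c(-90, 90),
                    seed = 4)
  sw$gain <- pmin(pmax(sw$gain, 0), 1)
  cd <- compare_decision_models(sw)
  curves <- cd[cd$scheme != "MLE", ]
  expect_equal(curves$scheme[which.max(curves$r.squared)], "PM")
})

test_that("the MAP curve fits monotone negative-slope data poorly", {
  # data spanning gains below 0.5 with monotonically falling gain-SD relation
  g <- seq(0.05, 0.95, by = 0.05)
  pts <- tibble::tibble(gain = g, sigma_res = scheme_sigma_curve(g, 12.5, "AS"))
  cd <- compare_decision_models(pts)
  r2 <- setNames(cd$r.squared, cd$scheme)
  expect_lt(r2[["MAP"]], 0.5)
  expect_gt(r2[["AS"]] - r2[["MAP"]], 0.4)
})

test_that("the constant-gain summary is the plain mean and sample SD", {
  expect_equal(mle_constant_gain(tibble::tibble(gain = c(1, 1, 1))),
               tibble::tibble(mean_gain = 1, sd_gain = 0, n = 3L))
  two <- mle_constant_gain(tibble::tibble(gain = c(0.8, 1.0)))
  expect_equal(two$mean_gain, 0.9)
  expect_equal(two$sd_gain, sd(c(0.8, 1.0)))
  # synthetic azimuth table recovers the generating gain
  study <- generate_snr_experiment(n_subjects = 3, seed = 17)
  az <- study_to_trials(study) |>
    regress_components(subject, condition, component) |>
    dplyr::filter(component == "az")
  expect_lt(abs(mle_constant_gain(az)$mean_gain - 0.9), 0.05)
})

test_that("the correlation comparison follows the Fisher r-to-z formula", {
  same <- compare_model_correlations(0.9, 0.9, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p.value, 1)
  # frozen textbook case: z = (atanh(.94) - atanh(.83)) / sqrt(2/27)
  cmp <- compare_model_correlations(0.94, 0.83, 30)
  expect_equal(cmp$z, 2.020509, tolerance = 1e-6)
  expect_equal(cmp$p.value, 0.0433306, tolerance = 1e-6)
  expect_error(compare_model_correlations(1, 0.5, 30))
  expect_error(compare_model_correlations(0.9, 0.5, 3))
})

test_that("Steiger's dependent-correlation variant behaves sensibly", {
  expect_error(compare_model_correlations(0.9, 0.8, 30, method = "steiger"),
               "r12")
  st <- compare_model_correlations(0.9, 0.8, 30, method = "steiger",
                                   r12 = 0.7)
  expect_true(is.finite(st$z))
  expect_gt(st$z, 0)
  # equal correlations still give z = 0
  eq <- compare_model_correlations(0.85, 0.85, 30, method = "steiger",
                                   r12 = 0.6)
  expect_equal(eq$z, 0)
})

test_that("model-comparison table stacks curve fits and the MLE row", {
  g <- c(0.2, 0.4, 0.6, 0.8)
  pts <- tibble::tibble(gain = g, sigma_res = scheme_sigma_curve(g, 11.5, "PM"))
  cd <- compare_decision_models(pts)
  expect_equal(cd$scheme, c("MAP", "AS", "PM", "MLE"))
  expect_true(is.na(cd$sigma_p[cd$scheme == "MLE"]))
  expect_equal(cd$mean_gain[cd$scheme == "MLE"], 0.5)
})
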