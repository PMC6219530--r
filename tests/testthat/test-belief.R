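test_that("posterior combination reproduces the worked single-trial example", {
  post <- posterior_combine(gaussian_belief(-6.3, 8), gaussian_belief(0, 11.5))
  # closed-form values from the shrinkage formulae at these inputs
  expect_equal(post$mean, -6.3 / (1 + 64 / 11.5^2), tolerance = 1e-12)
  expect_equal(post$sd, sqrt(64 / (1 + 64 / 11.5^2)), tolerance = 1e-12)
  # printed at 1 d.p. these are -4.2/-4.3 and 6.5/6.6 (the published example
  # rounds an unrounded noise realisation); agree within one printed unit
  expect_lt(abs(post$mean - (-4.3)), 0.1)
  expect_lt(abs(post$sd - 6.5), 0.1)
})

test_that("flat and symmetric limits of posterior combination are exact", {
  lik <- gaussian_belief(-6.3, 8)
  flat <- gaussian_belief(0, Inf)
  expect_identical(posterior_combine(lik, flat), lik)
  expect_identical(posterior_combine(flat, lik), lik)
  expect_error(posterior_combine(flat, flat), "undefined")
  # equal SDs and zero-mean prior: mean halves, sd shrinks by sqrt(2)
  eq <- posterior_combine(gaussian_belief(10, 6), gaussian_belief(0, 6))
  expect_equal(eq$mean, 5)
  expect_equal(eq$sd, 6 / sqrt(2))
})

test_that("posterior combination matches the gridded-density oracle", {
  cases <- list(c(-6.3, 8, 0, 11.5), c(12, 3, -5, 20), c(0.5, 25, 2, 4),
                c(-40, 15, 10, 15))
  for (cs in cases) {
    post <- posterior_combine(gaussian_belief(cs[1], cs[2]),
                              gaussian_belief(cs[3], cs[4]))
    oracle <- grid_product_posterior(cs[1], cs[2], cs[3], cs[4])
    expect_equal(post$mean, oracle$mean, tolerance = 1e-6)
    expect_equal(post$sd, oracle$sd, tolerance = 1e-5)
    expect_equal(post$mean, oracle$mode, tolerance = 1e-2)
  }
})

test_that("precision additivity and SD ordering hold across random beliefs", {
  withr::with_seed(11, {
    for (i in 1:50) {
      sd_l <- runif(1, 0.5, 40)
      sd_p <- runif(1, 0.5, 40)
      post <- posterior_combine(gaussian_belief(runif(1, -60, 60), sd_l),
                                gaussian_belief(0, sd_p))
      expect_equal(1 / post$sd^2, 1 / sd_l^2 + 1 / sd_p^2, tolerance = 1e-12)
      expect_lt(post$sd, min(sd_l, sd_p))
    }
  })
})

test_that("MAP gain follows the shrinkage factor and its limits", {
  expect_equal(round(map_gain(8, 11.5), 2), 0.67)
  expect_equal(map_gain(0, 5), 1)
  expect_equal(map_gain(7, 7), 0.5)
  expect_equal(map_gain(c(0, 7, 1000), Inf), c(1, 1, 1)) # MLE flat-prior limit
  g <- map_gain(seq(0, 50, by = 0.5), 11.5)
  expect_true(all(diff(g) < 0 | seq(0, 50, by = 0.5)[-1] == 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(map_gain(8, -1), "positive")
})

test_that("MAP gain-variance curve has the documented shape", {
  expect_equal(map_sigma_curve(0.5, 11.5), 5.75)
  expect_equal(map_sigma_curve(c(0, 1), 20), c(0, 0))
  # predicted response SD at the worked example's gain: 5.4 deg at 1 d.p.
  expect_equal(round(map_sigma_curve(map_gain(8, 11.5), 11.5), 1), 5.4)
  expect_error(map_sigma_curve(1.2, 10), "0, 1")
  # maximum sits at G = 0.5
  g <- seq(0, 1, by = 1e-4)
  expect_equal(g[which.max(map_sigma_curve(g, 11.5))], 0.5, tolerance = 1e-3)
  expect_equal(max(map_sigma_curve(g, 11.5)), 11.5 / 2, tolerance = 1e-7)
})

test_that("MAP predicted SD equals G * sigma_t, below the posterior SD", {
  for (st in c(2, 8, 20)) {
    g <- map_gain(st, 11.5)
    expect_equal(map_sigma_curve(g, 11.5), g * st, tolerance = 1e-12)
    expect_lt(map_sigma_curve(g, 11.5), sqrt(g) * st) # sigma_MAP < sigma_POST
  }
})

test_that("AS and PM gain-variance curves hit their endpoints and algebra", {
  expect_equal(as_gain_curve(12.5, 12.5), 0)
  expect_equal(as_gain_curve(0, 12.5), 1)
  expect_equal(as_gain_curve(12.5 / sqrt(2), 12.5), 0.5)
  expect_equal(pm_gain_curve(11.5, 11.5), 0)
  expect_equal(pm_gain_curve(0, 11.5), 1)
  expect_error(as_gain_curve(13, 12.5), "negative gain")
  expect_error(pm_gain_curve(13, 12.5), "negative gain")
  # AS is linear in variance: gain drops by sigma^2/sigma_p^2
  s <- seq(0, 11.5, length.out = 7)
  expect_equal(as_gain_curve(s, 11.5), 1 - s^2 / 11.5^2)
})

test_that("the MAP curve is recovered by eliminating sigma_t from gain and SD", {
  # across a noise grid, (map_gain, G * sigma_t) must land on map_sigma_curve
  st <- seq(0.5, 80, by = 0.5)
  for (sp in c(5, 11.5, 23.8)) {
    g <- map_gain(st, sp)
    expect_equal(g * st, map_sigma_curve(g, sp), tolerance = 1e-10)
  }
})

test_that("belief and prior constructors enforce their invariants", {
  expect_error(gaussian_belief(0, 0), "positive")
  expect_error(gaussian_belief(0, -2), "positive")
  expect_error(gaussian_belief(Inf, 5))
  expect_error(spatial_prior(azimuth_sd = 5, elevation_sd = 11.5), "wide")
  sp <- spatial_prior(Inf, 11.5)
  expect_equal(sp$azimuth$mean, 0)
  expect_equal(sp$elevation$sd, 11.5)
})
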