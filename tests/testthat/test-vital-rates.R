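test_that("nest survival follows the saturating form", {
  cv <- survival_curve() # f_max = 0.85, s_half = 42
  expect_equal(nest_survival(0, cv), 0)
  expect_equal(nest_survival(42, cv), 0.425) # half saturation
  # frozen high-precision evaluation at s = 100
  expect_equal(nest_survival(100, cv), 0.598591549295774648, tolerance = 1e-12)
  # strictly increasing, bounded by f_max
  s <- exp(seq(log(0.1), log(1e6), length.out = 200))
  f <- nest_survival(s, cv)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < cv$f_max))
  expect_equal(nest_survival(1e6, cv), cv$f_max, tolerance = 1e-4)
  expect_error(nest_survival(-1, cv), ">= 0")
})

test_that("saturation density has the documented orientation behaviour", {
  dec <- density_curve() # l = 0.13, alpha = 0.18, t = 13.4, decreasing
  lit <- density_curve(orientation = "literal")
  # midpoint identical under both orientations
  expect_equal(saturation_density(13.4, dec), (1 + 0.13) / 2)
  expect_equal(saturation_density(13.4, lit), (1 + 0.13) / 2)
  # frozen high-precision evaluation at s = 10 (decreasing)
  expect_equal(saturation_density(10, dec), 0.694105297795281661,
               tolerance = 1e-12)
  # asymptotes: decreasing falls to l, literal rises to 1
  expect_equal(saturation_density(1000, dec), 0.13, tolerance = 1e-8)
  expect_equal(saturation_density(1e6, dec), 0.13, tolerance = 1e-10)
  expect_equal(saturation_density(1e6, lit), 1, tolerance = 1e-10)
  # strictly monotone where the curve is numerically resolvable; never the
  # wrong direction even far into the asymptote
  s <- seq(0, 80, length.out = 100)
  expect_true(all(diff(saturation_density(s, dec)) < 0))
  expect_true(all(diff(saturation_density(s, lit)) > 0))
  s_wide <- seq(0, 500, length.out = 100)
  expect_true(all(diff(saturation_density(s_wide, dec)) <= 0))
  expect_true(all(diff(saturation_density(s_wide, lit)) >= 0))
  expect_error(saturation_density(-2, dec), ">= 0")
})

test_that("survival-curve fitting recovers parameters", {
  s <- exp(seq(log(1), log(500), length.out = 20))
  truth <- survival_curve(0.85, 42)
  obs <- vital_obs(s, nest_survival(s, truth), "survival")
  # noiseless self-consistency
  fit <- fit_survival_curve(obs)
  expect_equal(fit$f_max, 0.85, tolerance = 1e-6)
  expect_equal(fit$s_half, 42, tolerance = 1e-6)
  # contracts
  expect_error(fit_survival_curve(obs[1:2, ]), ">= 3")
  one_size <- vital_obs(rep(10, 5), rep(0.2, 5), "survival")
  expect_error(fit_survival_curve(one_size), "single patch size")
  # noisy recovery at the stated design: 200 points, sd 0.05
  obs_n <- generate_vital_observations(truth, sizes = exp(seq(log(1), log(500),
                                                              length.out = 200)),
                                       noise_sd = c(survival = 0.05, density = 0),
                                       seed = 42)
  fit_n <- fit_survival_curve(obs_n[obs_n$kind == "survival", ])
  expect_lt(abs(fit_n$f_max - 0.85) / 0.85, 0.10)
  expect_lt(abs(fit_n$s_half - 42) / 42, 0.10)
})

test_that("density-curve fitting recovers parameters in both orientations", {
  s <- exp(seq(log(0.5), log(400), length.out = 30))
  truth <- density_curve(0.13, 0.18, 13.4)
  obs <- vital_obs(s, saturation_density(s, truth), "density")
  fit <- fit_density_curve(obs)
  expect_equal(fit$l, 0.13, tolerance = 1e-5)
  expect_equal(fit$alpha, 0.18, tolerance = 1e-5)
  expect_equal(fit$t, 13.4, tolerance = 1e-5)
  # alternative truth
  truth2 <- density_curve(0.2, 0.5, 50)
  obs2 <- vital_obs(s, saturation_density(s, truth2), "density")
  fit2 <- fit_density_curve(obs2)
  expect_equal(fit2$alpha, 0.5, tolerance = 1e-5)
  expect_equal(fit2$t, 50, tolerance = 1e-5)
  # literal orientation round trip
  lit <- density_curve(0.13, 0.18, 13.4, orientation = "literal")
  obs3 <- vital_obs(s, saturation_density(s, lit), "density")
  fit3 <- fit_density_curve(obs3, orientation = "literal")
  expect_equal(fit3$t, 13.4, tolerance = 1e-4)
  expect_error(fit_density_curve(obs[1:2, ]), ">= 4")
})

test_that("observations validate their ranges and round-trip through csv", {
  expect_error(vital_obs(c(1, -2), c(0.1, 0.2), "survival"), "> 0")
  expect_error(vital_obs(c(1, 2), c(0.1, 1.2), "survival"), "\\[0, 1\\]")
  expect_error(vital_obs(c(1, 2), c(0.1, -0.2), "density"), ">= 0")
  obs <- vital_obs(c(1, 10, 100), c(0.1, 0.2, 0.5), "survival")
  f <- write_tmp_csv(obs)
  back <- load_vital_obs(f)
  expect_equal(back$patch_size_ha, obs$patch_size_ha)
  expect_equal(back$value, obs$value)
})
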