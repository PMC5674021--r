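test_that("square-core geometry gives the closed-form quality", {
  # 1-ha square patch: 100 m side, 40 m core side, 0.16 ha core
  expect_equal(fragdd:::square_core_area(1, 30), 0.16)
  # core vanishes for patches smaller than the buffer allows
  expect_equal(fragdd:::square_core_area(0.3, 30), 0)
  # single-patch quality is monotone increasing in patch area
  a <- 10^seq(-0.3, 4, length.out = 50)
  q <- fragdd:::square_core_area(a, 30) / a
  expect_true(all(diff(q) > 0))
  # huge patches approach Q = 1
  expect_gt(fragdd:::square_core_area(1e4, 30) / 1e4, 0.97)
})

test_that("generated landscapes are deterministic and respect the config", {
  cfg <- landscape_gen_config(n_landscapes = 3, n_patches = 500,
                              mu_gradient = c(1, 2, 3), seed = 7)
  l1 <- generate_landscape(cfg, mu = 2, id = "X")
  l2 <- generate_landscape(cfg, mu = 2, id = "X")
  expect_identical(l1, l2)
  l3 <- generate_landscape(cfg, mu = 2, id = "X", seed = 8)
  expect_false(identical(l1$quality, l3$quality))
  # common total area and Q in bounds
  expect_equal(total_area(l1$forest), cfg$total_area_ha, tolerance = 1e-9)
  expect_true(l1$quality >= 0 && l1$quality <= 1)
  # a landscape of huge patches is nearly all core
  big <- generate_landscape(landscape_gen_config(n_landscapes = 1,
                                                 n_patches = 200,
                                                 mu_gradient = log(2e4),
                                                 sigma = 0.2, seed = 1),
                            mu = log(2e4), id = "BIG")
  expect_gt(big$quality, 0.97)
})

test_that("the fragmentation gradient orders quality by mu", {
  cfg <- landscape_gen_config(n_landscapes = 3, n_patches = 5000,
                              mu_gradient = c(1, 3, 5), seed = 11)
  lands <- generate_fragmentation_gradient(cfg)
  q <- vapply(lands, function(l) l$quality, numeric(1))
  expect_true(all(diff(q) > 0))
  # second seed: different realization, same ordering
  cfg2 <- landscape_gen_config(n_landscapes = 3, n_patches = 5000,
                               mu_gradient = c(1, 3, 5), seed = 99)
  lands2 <- generate_fragmentation_gradient(cfg2)
  q2 <- vapply(lands2, function(l) l$quality, numeric(1))
  expect_false(identical(q, q2))
  expect_true(all(diff(q2) > 0))
})

test_that("vital observations reproduce the curves at zero noise", {
  sizes <- c(1, 5, 20, 100, 400)
  obs <- generate_vital_observations(sizes = sizes,
                                     noise_sd = c(survival = 0, density = 0),
                                     seed = 3)
  sv <- obs[obs$kind == "survival", ]
  dv <- obs[obs$kind == "density", ]
  expect_equal(sv$value, nest_survival(sizes))
  expect_equal(dv$value, saturation_density(sizes))
  # determinism under seed
  obs2 <- generate_vital_observations(sizes = sizes, seed = 5)
  obs3 <- generate_vital_observations(sizes = sizes, seed = 5)
  expect_identical(obs2, obs3)
})

test_that("trend scenarios round-trip through annual_trend at zero noise", {
  summaries <- data.frame(landscape_id = c("A", "B", "C"),
                          b_prime = c(0.5, 1, 3))
  cfg <- trend_scenario_config("nonbreeding", delta_M = 0.1, d_prime = 1,
                               noise_sd = 0, seed = 2)
  series <- generate_trend_scenario(summaries, cfg)
  for (id in summaries$landscape_id) {
    tr <- annual_trend(series[series$landscape_id == id, ])
    want <- predicted_change(summaries$b_prime[summaries$landscape_id == id],
                             cfg$season)
    expect_equal(tr$magnitude, want, tolerance = 1e-12)
    expect_lte(tr$trend, 0) # scenario shifts are declines
  }
  # no shifts at all: flat series
  flat_cfg <- trend_scenario_config("mixed", delta_F = 0, delta_M = 0,
                                    d_prime = 1, noise_sd = 0, seed = 2)
  flat <- generate_trend_scenario(summaries, flat_cfg)
  expect_true(all(abs(flat$index - 100) < 1e-12))
  # spread b' under the nonbreeding scenario implies a negative rank relation
  mags <- vapply(split(series, series$landscape_id),
                 function(s) annual_trend(s)$magnitude, numeric(1))
  expect_equal(cor(summaries$b_prime, mags[summaries$landscape_id],
                   method = "spearman"), -1)
})

test_that("synthetic landscapes survive the patch-table round trip", {
  cfg <- landscape_gen_config(n_landscapes = 2, n_patches = 800,
                              mu_gradient = c(1.5, 3.5), seed = 21)
  lands <- generate_fragmentation_gradient(cfg)
  f <- tempfile(fileext = ".csv")
  write_patch_table(lands, f)
  recs <- load_patch_table(f)
  for (l in lands) {
    back <- aggregate_counties(recs, l$id, "total")
    expect_equal(back$classes$total_area_ha, l$forest$classes$total_area_ha,
                 tolerance = 1e-9)
    expect_equal(back$classes$mean_size_ha, l$forest$classes$mean_size_ha,
                 tolerance = 1e-9)
    core_back <- aggregate_counties(recs, l$id, "core")
    expect_equal(landscape_quality(total_area(core_back), total_area(back)),
                 l$quality, tolerance = 1e-9)
  }
})
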