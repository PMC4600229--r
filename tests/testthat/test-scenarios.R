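test_that("the scenario catalog encodes every reported structural number", {
  cat0 <- scenario_catalog()
  expect_named(cat0, c("baseline_best", "baseline_worst", "edta",
                       "lactoferrin", "lysozyme_before", "lysozyme_after"))

  best <- cat0$baseline_best$truth
  am <- asymmetry_metrics(best)
  expect_equal(am$outer_ratio, "79:11")
  expect_equal(am$inner_ratio, "8:82")
  expect_equal(best$water_gap, 15)
  expect_equal(best$t_core, 30)
  expect_gt(best$coverage, 0.90)
  expect_equal(best$sigma_bilayer, 9.31)
  expect_true(best$t_inner_tail >= 14 && best$t_inner_tail <= 18)
  expect_true(best$t_outer_tail >= 14 && best$t_outer_tail <= 18)

  amw <- asymmetry_metrics(cat0$baseline_worst$truth)
  expect_equal(amw$outer_ratio, "69:28")
  expect_equal(amw$inner_ratio, "23:75")

  # EDTA: both dominant fractions fall by 20 points
  ch <- asymmetry_change(best, cat0$edta$truth)
  expect_equal(ch$outer_delta_pct, -20)
  expect_equal(ch$inner_delta_pct, -20)

  # lactoferrin: 90 A protein layer, coverage down 12 points, outer LPS
  # down 30 points
  lac <- cat0$lactoferrin$truth
  expect_equal(lac$protein$thickness, 90)
  expect_equal(best$coverage - lac$coverage, 0.12)
  expect_equal(asymmetry_change(best, lac)$outer_delta_pct, -30)

  # lysozyme: before is the baseline; after gains 20 A of core and the
  # roughness moves 9.31 -> 12.88 with no coverage loss
  lb <- cat0$lysozyme_before$truth
  la <- cat0$lysozyme_after$truth
  expect_equal(fsbnr:::model_get_params(lb, default_free(lb)),
               fsbnr:::model_get_params(best, default_free(best)))
  expect_equal(la$t_core - lb$t_core, 20)
  expect_equal(lb$sigma_bilayer, 9.31)
  expect_equal(la$sigma_bilayer, 12.88)
  expect_equal(la$coverage, lb$coverage)
})

test_that("unknown scenario names fail loudly", {
  expect_error(fsbnr:::get_scenario("lysozyme"), "valid names")
})

test_that("the generator is exact at zero noise and seeded otherwise", {
  sc <- scenario_catalog()$baseline_best
  sc$instrument <- tiny_instrument()

  ds0 <- generate_datasets(sc, seed = 3, noise_level = 0)
  for (i in seq_along(ds0)) {
    curve <- measured_curve(build_slabs(sc$truth, sc$contrasts[[i]]),
                            sc$instrument, warn_roughness = FALSE)
    expect_equal(ds0[[i]]$r, curve, tolerance = 1e-12)
    expect_true(all(ds0[[i]]$dr > 0))
  }

  d1 <- generate_datasets(sc, seed = 9)
  d2 <- generate_datasets(sc, seed = 9)
  d3 <- generate_datasets(sc, seed = 10)
  expect_identical(d1, d2)
  expect_false(identical(d1[[1]]$r, d3[[1]]$r))

  expect_error(generate_datasets(sc, seed = 1, noise_level = -0.1),
               "noise_level")
})

test_that("generator residuals are standard normal across the curve", {
  sc <- scenario_catalog()$baseline_best
  ds <- generate_datasets(sc, seed = 123)
  z <- unlist(lapply(seq_along(ds), function(i) {
    curve <- measured_curve(build_slabs(sc$truth, sc$contrasts[[i]]),
                            sc$instrument, warn_roughness = FALSE)
    (ds[[i]]$r - curve) / ds[[i]]$dr
  }))
  expect_gte(length(z), 400)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(stats::var(z) - 1), 3 * sqrt(2 / length(z)))
})

test_that("a noiseless single-replicate recovery is unbiased", {
  sc <- scenario_catalog()$baseline_best
  sc$instrument <- tiny_instrument()
  rec <- recovery_experiment(sc, n_replicates = 1, seed = 2,
                             noise_level = 0, perturb = 0.05,
                             intervals = FALSE,
                             control = fsb_control(global = FALSE,
                                                   nm_maxit = 300,
                                                   nm_restarts = 3))
  expect_true(all(abs(rec$summary$bias) <
                    0.01 * pmax(abs(rec$summary$truth), 0.1)))
})

test_that("estimate RMSE grows with the noise level", {
  sc <- scenario_catalog()$baseline_best
  sc$instrument <- tiny_instrument()
  ctl <- fsb_control(global = FALSE, nm_maxit = 300, nm_restarts = 3)
  rec_hi <- recovery_experiment(sc, n_replicates = 3, seed = 31,
                                noise_level = 0.08, intervals = FALSE,
                                control = ctl)
  rec_lo <- recovery_experiment(sc, n_replicates = 3, seed = 31,
                                noise_level = 0.01, intervals = FALSE,
                                control = ctl)
  hi <- rec_hi$summary; lo <- rec_lo$summary
  key <- c("water_gap", "t_core", "sigma_bilayer")
  expect_true(all(hi$rmse[match(key, hi$parameter)] >
                    lo$rmse[match(key, lo$parameter)]))
})
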