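# small, fast scenario used throughout: fewer q points, two contrasts
fit_fixture <- function(noise = 0.03, seed = 5, n_contrasts = 4) {
  sc <- scenario_catalog()$baseline_best
  sc$instrument <- tiny_instrument()
  sc$contrasts <- default_contrasts()[seq_len(n_contrasts)]
  list(sc = sc, ds = generate_datasets(sc, seed = seed,
                                       noise_level = noise))
}

test_that("the objective is an error-weighted sum of squares", {
  fx <- fit_fixture(noise = 0)
  m <- fx$sc$truth

  # exact model curve: objective vanishes
  expect_lt(fsb_objective(m, fx$ds, fx$sc$instrument), 1e-10)

  fx2 <- fit_fixture(noise = 0.05)
  o1 <- fsb_objective(m, fx2$ds, fx2$sc$instrument)
  expect_gt(o1, 0)

  # doubling every dR quarters the objective
  ds_wide <- lapply(fx2$ds, function(d) { d$dr <- 2 * d$dr; d })
  expect_equal(fsb_objective(m, ds_wide, fx2$sc$instrument), o1 / 4,
               tolerance = 1e-4)

  # additivity across datasets
  o_each <- vapply(fx2$ds, function(d)
    fsb_objective(m, list(d), fx2$sc$instrument), numeric(1))
  expect_equal(sum(o_each), o1, tolerance = 1e-8)

  expect_error(fsb_objective(m, list(), fx2$sc$instrument), "empty")
})

test_that("the generator noise model is chi-square consistent at the truth", {
  sc <- scenario_catalog()$baseline_best
  ds <- generate_datasets(sc, seed = 77)
  chi2 <- fsb_objective(sc$truth, ds, sc$instrument,
                        fit_scale = FALSE, fit_background = FALSE)
  dof <- sum(vapply(ds, function(d) length(d$q), numeric(1)))
  expect_lt(abs(chi2 - dof), 3 * sqrt(2 * dof))
})

test_that("a fit started at the truth of noiseless data stays there", {
  fx <- fit_fixture(noise = 0)
  fit <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                 seed = 1, control = fsb_control(global = FALSE),
                 intervals = FALSE)
  expect_lt(fit$objective, 1e-6)
  truth <- coef(fit)
  for (nm in names(truth))
    expect_equal(truth[[nm]],
                 fsbnr:::model_get_params(fx$sc$truth, nm)[[1]],
                 tolerance = 0.01)
  expect_equal(unname(fit$scale), rep(1, length(fx$ds)), tolerance = 1e-3)
})

test_that("co-refinement is bit-reproducible given the seed", {
  fx <- fit_fixture()
  ctl <- fsb_control(global = FALSE, nm_maxit = 150, nm_restarts = 2)
  f1 <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                seed = 42, control = ctl, n_resamples = 30)
  f2 <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                seed = 42, control = ctl, n_resamples = 30)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$intervals, f2$intervals)
})

test_that("fits and intervals are invariant to dataset ordering", {
  fx <- fit_fixture()
  ctl <- fsb_control(global = FALSE, nm_maxit = 150, nm_restarts = 2)
  f1 <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                seed = 42, control = ctl, n_resamples = 30)
  f2 <- fsb_fit(rev(fx$ds), model = fx$sc$truth,
                instrument = fx$sc$instrument,
                seed = 42, control = ctl, n_resamples = 30)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$intervals, f2$intervals)
})

test_that("the local stage never worsens the starting objective", {
  fx <- fit_fixture()
  free <- default_free(fx$sc$truth)
  start <- fsbnr:::model_get_params(fx$sc$truth, free) * 1.1
  b <- default_bounds(fx$sc$truth, free)
  start <- pmin(pmax(start, b$lower), b$upper)
  sm <- fsbnr:::model_set_params(fx$sc$truth, setNames(start, free))
  f_start <- fsb_objective(sm, fx$ds, fx$sc$instrument)
  fit <- fsb_fit(fx$ds, model = sm, instrument = fx$sc$instrument,
                 seed = 2, control = fsb_control(global = FALSE,
                                                 nm_maxit = 200,
                                                 nm_restarts = 2),
                 intervals = FALSE)
  expect_lte(fit$objective, f_start)
})

test_that("fit configuration is validated", {
  fx <- fit_fixture()
  expect_error(fsb_fit(list(), model = fx$sc$truth), "empty")
  expect_error(fsb_fit(fx$ds, model = fx$sc$truth, free = character(0)),
               "no parameter marked free")
  bad <- fx$ds
  bad[[1]]$r[5] <- NaN
  expect_error(fsb_fit(bad, model = fx$sc$truth, seed = 1,
                       control = fsb_control(global = FALSE)),
               "non-finite")
})

test_that("bootstrap intervals bracket the estimate and shrink with noise", {
  fx <- fit_fixture(noise = 0.03)
  ctl <- fsb_control(global = FALSE, nm_maxit = 200, nm_restarts = 2)
  fit <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                 seed = 3, control = ctl, n_resamples = 50)
  iv <- fit$intervals
  expect_true(all(iv$low <= iv$estimate + 1e-12))
  expect_true(all(iv$high >= iv$estimate - 1e-12))
  expect_true(all(fit$derived$low <= fit$derived$estimate + 1e-12))

  # near-zero noise: interval widths collapse
  fx0 <- fit_fixture(noise = 1e-4)
  fit0 <- fsb_fit(fx0$ds, model = fx0$sc$truth,
                  instrument = fx0$sc$instrument,
                  seed = 3, control = ctl, n_resamples = 50)
  w <- fit$intervals$high - fit$intervals$low
  w0 <- fit0$intervals$high - fit0$intervals$low
  common <- intersect(fit$intervals$parameter, fit0$intervals$parameter)
  i <- match(common, fit$intervals$parameter)
  i0 <- match(common, fit0$intervals$parameter)
  expect_true(all(w0[i0] < 0.05 * w[i] + 1e-10))

  expect_error(fsb_confint(fit, n_resamples = 10), "at least 20")
})

test_that("more contrasts tighten the leaflet-fraction intervals", {
  ctl <- fsb_control(global = FALSE, nm_maxit = 200, nm_restarts = 2)
  fx4 <- fit_fixture(seed = 9, n_contrasts = 4)
  f4 <- fsb_fit(fx4$ds, model = fx4$sc$truth,
                instrument = fx4$sc$instrument, seed = 4,
                control = ctl, n_resamples = 80)
  f1 <- fsb_fit(fx4$ds[1], model = fx4$sc$truth,
                instrument = fx4$sc$instrument, seed = 4,
                control = ctl, n_resamples = 80)
  width <- function(f, p) {
    r <- f$intervals[f$intervals$parameter == p, ]
    r$high - r$low
  }
  expect_lt(width(f4, "outer_f_lps"), width(f1, "outer_f_lps"))
  expect_lt(width(f4, "inner_f_pc"), width(f1, "inner_f_pc"))
})

test_that("posterior sampling offers an alternative interval route", {
  fx <- fit_fixture()
  ctl <- fsb_control(global = FALSE, nm_maxit = 200, nm_restarts = 2)
  fit <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                 seed = 3, control = ctl, intervals = FALSE)
  fit <- fsb_confint(fit, method = "posterior", n_resamples = 50, seed = 8)
  iv <- fit$intervals
  expect_true(all(iv$low <= iv$estimate & iv$estimate <= iv$high))
  expect_equal(fit$interval_method, "posterior")
})

test_that("fit methods expose curves, residuals and simulations", {
  fx <- fit_fixture()
  ctl <- fsb_control(global = FALSE, nm_maxit = 200, nm_restarts = 2)
  fit <- fsb_fit(fx$ds, model = fx$sc$truth, instrument = fx$sc$instrument,
                 seed = 3, control = ctl, n_resamples = 30)

  pr <- predict(fit)
  expect_length(pr, length(fx$ds))
  expect_named(pr[[1]], c("q", "r_obs", "dr", "r_fit"))

  res <- residuals(fit)
  expect_equal(length(unlist(res)), fit$n_points)
  expect_lt(abs(mean(unlist(res))), 0.2)

  sim <- simulate(fit, nsim = 2, seed = 11)
  expect_length(sim, 2)
  expect_false(identical(sim[[1]][[1]]$r, sim[[2]][[1]]$r))
  expect_identical(sim[[1]][[1]]$q, fit$datasets[[1]]$q)

  out <- utils::capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("range", out)))
  expect_true(any(grepl("LPS:PC", out)))
})
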