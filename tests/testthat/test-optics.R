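test_that("bare-interface reflectivity reproduces the Fresnel closed form", {
  # Si fronting against D2O backing: total external reflection below the
  # critical edge q_c = sqrt(16 pi drho)
  rho_si <- 2.07; rho_d2o <- 6.38
  p <- slab_profile(numeric(0), numeric(0), numeric(0), rho_si, rho_d2o)
  qc <- sqrt(16 * pi * (rho_d2o - rho_si) * 1e-6)
  expect_equal(qc, 0.0147, tolerance = 0.002)

  q_below <- seq(0.002, qc * 0.98, length.out = 20)
  expect_equal(reflectivity(p, q_below), rep(1, 20))

  # independent closed form above the edge
  q_above <- seq(qc * 1.05, 0.3, length.out = 40)
  kz0 <- q_above / 2
  kz1 <- sqrt(kz0^2 - 4 * pi * (rho_d2o - rho_si) * 1e-6)
  r_fresnel <- ((kz0 - kz1) / (kz0 + kz1))^2
  expect_equal(reflectivity(p, q_above), r_fresnel, tolerance = 1e-12)
})

test_that("matrix and recursion engines agree to numerical precision", {
  q <- exp(seq(log(0.005), log(0.35), length.out = 80))
  set.seed(31)
  for (k in 1:30) {
    p <- random_stack(sample(1:6, 1))
    r_mat <- reflectivity(p, q, method = "abeles", warn_roughness = FALSE)
    r_rec <- reflectivity(p, q, method = "parratt", warn_roughness = FALSE)
    expect_lt(max(abs(r_mat - r_rec) / pmax(r_mat, 1e-14)), 1e-10)
    expect_true(all(r_mat >= 0 & r_mat <= 1))
  }
})

test_that("zero-thickness layers and matched media are optically invisible", {
  q <- exp(seq(log(0.008), log(0.3), length.out = 60))
  p <- slab_profile(c(80, 20), c(4.5, 1.2), c(0, 0), 2.07, 6.38, 0)
  r0 <- reflectivity(p, q)

  # smooth stack: an extra zero-thickness layer of any SLD changes nothing
  p_ins <- slab_profile(c(80, 0, 20), c(4.5, 8.8, 1.2), c(0, 0, 0),
                        2.07, 6.38, 0)
  expect_equal(reflectivity(p_ins, q), r0, tolerance = 1e-13)

  # rough stack: a zero-thickness layer matching its neighbour's SLD
  # (carrying that neighbour's interface roughness) changes nothing
  pr <- slab_profile(c(80, 20), c(4.5, 1.2), c(3, 5), 2.07, 6.38, 4)
  pr_ins <- slab_profile(c(80, 0, 20), c(4.5, 4.5, 1.2), c(3, 0, 5),
                         2.07, 6.38, 4)
  expect_equal(reflectivity(pr_ins, q, warn_roughness = FALSE),
               reflectivity(pr, q, warn_roughness = FALSE),
               tolerance = 1e-13)

  # contrast-matched stack: as all SLDs approach the fronting value the
  # reflectivity vanishes pointwise
  fade <- vapply(c(1, 0.1, 0.01), function(eps) {
    pe <- slab_profile(c(80, 20), 2.07 + eps * c(2.43, -0.87),
                       c(0, 0), 2.07, 2.07 + eps * 4.31, 0)
    max(reflectivity(pe, q))
  }, numeric(1))
  expect_true(all(diff(fade) < 0))
  expect_lt(fade[3], 1e-4)
})

test_that("reflectivity validates its inputs", {
  p <- slab_profile(c(30), c(4), c(2), 2.07, 6.38, 2)
  expect_error(reflectivity(p, c(-0.01, 0.1)), "positive")
  p$layers$thickness[1] <- -5
  expect_error(reflectivity(p, 0.1), "negative")
  pr <- slab_profile(c(10), c(4), c(8), 2.07, 6.38, 0)
  expect_warning(reflectivity(pr, 0.1), "roughness exceeds")
})

test_that("resolution smearing is a proper Gaussian convolution", {
  q <- exp(seq(log(0.008), log(0.3), length.out = 400))
  p <- build_slabs(fsb_model(), contrast_condition(1, "up"))
  r <- reflectivity(p, q, warn_roughness = FALSE)

  expect_identical(smear(r, q, 0), r)
  expect_equal(smear(rep(0.37, length(q)), q, 0.05),
               rep(0.37, length(q)), tolerance = 1e-12)

  # against a dense brute-force quadrature at interior points
  rs <- smear(r, q, 0.04)
  sigma_rel <- 0.04 / (2 * sqrt(2 * log(2)))
  idx <- seq(60, 340, by = 40)
  for (i in idx) {
    s <- sigma_rel * q[i]
    qq <- seq(q[i] - 3 * s, q[i] + 3 * s, length.out = 1501)
    rr <- reflectivity(p, qq, warn_roughness = FALSE)
    w <- exp(-0.5 * ((qq - q[i]) / s)^2)
    expect_equal(rs[i], sum(w * rr) / sum(w), tolerance = 0.02)
  }

  # smearing preserves monotonicity through the critical edge
  pf <- slab_profile(numeric(0), numeric(0), numeric(0), 2.07, 6.38)
  qf <- seq(0.005, 0.05, length.out = 300)
  rf <- smear(reflectivity(pf, qf), qf, 0.04)
  expect_true(all(diff(rf) < 1e-9))

  expect_error(smear(r, q, -0.01), "dq_over_q")
})

test_that("measured curves apply scale, background and resolution", {
  p <- build_slabs(fsb_model(), contrast_condition(1, "up"))
  q <- exp(seq(log(0.008), log(0.3), length.out = 60))

  raw <- nr_instrument(q_grid = q, dq_over_q = 0, background = 0, scale = 1)
  expect_equal(measured_curve(p, raw, warn_roughness = FALSE),
               reflectivity(p, q, warn_roughness = FALSE))

  # background dominates the tail
  bg <- nr_instrument(q_grid = q, background = 1e-4)
  tail_val <- utils::tail(measured_curve(p, bg, warn_roughness = FALSE), 3)
  expect_equal(tail_val, rep(1e-4, 3), tolerance = 0.05)

  # linearity in the scale factor
  i1 <- nr_instrument(q_grid = q, background = 1e-6, scale = 1)
  i2 <- nr_instrument(q_grid = q, background = 1e-6, scale = 2)
  c1 <- measured_curve(p, i1, warn_roughness = FALSE)
  c2 <- measured_curve(p, i2, warn_roughness = FALSE)
  expect_equal(c2 - 1e-6, 2 * (c1 - 1e-6), tolerance = 1e-12)

  expect_error(nr_instrument(q_grid = c(0.2, 0.1)), "increasing")
  expect_error(nr_instrument(scale = 0), "scale")
})
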