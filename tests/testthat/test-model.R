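test_that("leaflet compositions enforce their closure invariant", {
  l <- leaflet_composition(0.79, 0.11)
  expect_equal(l$f_solvent, 0.10)
  expect_error(leaflet_composition(0.8, 0.3, 0.2), "sum to 1")
  expect_error(leaflet_composition(-0.1, 0.9, 0.2), "\\[0, 1\\]")
})

test_that("model constructor rejects unphysical structures", {
  expect_error(fsb_model(water_gap = -2), "thicknesses")
  expect_error(fsb_model(coverage = 1.2), "coverage")
  expect_error(fsb_model(sigma_bilayer = -1), "sigma_bilayer")
  expect_error(add_protein_layer(fsb_model(), -5, 0.3), "thickness")
  expect_error(add_protein_layer(fsb_model(), 90, 1.3), "fraction")
  expect_error(add_protein_layer(fsb_model(), 90, 0.3, "unobtainium"),
               "unknown material")
})

test_that("asymmetry metrics render the LPS:PC convention and round-trip", {
  best <- fsb_model()
  am <- asymmetry_metrics(best)
  expect_equal(am$outer_ratio, "79:11")
  expect_equal(am$inner_ratio, "8:82")

  worst <- fsb_model(outer = leaflet_composition(0.69, 0.28, 0.03),
                     inner = leaflet_composition(0.23, 0.75, 0.02))
  amw <- asymmetry_metrics(worst)
  expect_equal(amw$outer_ratio, "69:28")
  expect_equal(amw$inner_ratio, "23:75")

  sym <- fsb_model(outer = leaflet_composition(0.5, 0.5, 0),
                   inner = leaflet_composition(0.5, 0.5, 0))
  expect_equal(asymmetry_metrics(sym)$outer_ratio, "50:50")

  # ratio strings round-trip to the stored fractions within half a point
  set.seed(21)
  for (k in 1:10) {
    f1 <- runif(1, 0.05, 0.85); f2 <- runif(1, 0.05, 0.9 - f1)
    m <- fsb_model(outer = leaflet_composition(f1, f2))
    parts <- as.numeric(strsplit(asymmetry_metrics(m)$outer_ratio,
                                 ":")[[1]])
    expect_lte(abs(parts[1] - 100 * f1), 0.5)
    expect_lte(abs(parts[2] - 100 * f2), 0.5)
    expect_true(all(parts >= 0 & parts <= 100))
  }
})

test_that("asymmetry change reports dominant-species shifts per leaflet", {
  before <- fsb_model()
  expect_equal(asymmetry_change(before, before),
               list(outer_delta_pct = 0, inner_delta_pct = 0))

  after <- fsb_model(outer = leaflet_composition(0.59, 0.31, 0.10),
                     inner = leaflet_composition(0.28, 0.62, 0.10))
  ch <- asymmetry_change(before, after)
  expect_equal(ch$outer_delta_pct, -20)
  expect_equal(ch$inner_delta_pct, -20)

  lacto <- fsb_model(outer = leaflet_composition(0.49, 0.41, 0.10))
  expect_equal(asymmetry_change(before, lacto)$outer_delta_pct, -30)

  # relative convention as the documented alternative
  rel <- asymmetry_change(before, lacto, relative = TRUE)
  expect_equal(rel$outer_delta_pct, 100 * (0.49 - 0.79) / 0.79)
})

test_that("slab profiles share structure across contrasts", {
  m <- fsb_model()
  p_d2o <- build_slabs(m, contrast_condition(1, "up"))
  p_h2o <- build_slabs(m, contrast_condition(0, "down"))

  expect_equal(p_d2o$layers$thickness, p_h2o$layers$thickness)
  expect_equal(p_d2o$layers$roughness, p_h2o$layers$roughness)
  expect_equal(p_d2o$layers$name, p_h2o$layers$name)

  differs <- p_d2o$layers$sld != p_h2o$layers$sld
  solvent_bearing <- p_d2o$layers$name %in%
    c("water_gap", "inner_head", "inner_tail", "outer_tail", "lps_core")
  magnetic <- p_d2o$layers$name == "permalloy"
  expect_true(all(differs == (solvent_bearing | magnetic)))

  # determinism: identical model + contrast give identical profiles
  expect_identical(p_d2o, build_slabs(m, contrast_condition(1, "up")))
})

test_that("layer SLDs follow the mixing rules", {
  mats <- load_materials()
  m <- fsb_model(materials = mats)
  d2o <- contrast_condition(1, "up")
  p <- build_slabs(m, d2o)
  lay <- p$layers
  rho <- function(nm) nuclear_sld(mats[[nm]])
  rs <- solvent_sld(d2o, mats)
  # independent recomputation of the outer-tail mixture
  within <- 0.79 * rho("lps_tails") + 0.11 * rho("dppc_tails_d") + 0.10 * rs
  expect_equal(lay$sld[lay$name == "outer_tail"],
               0.93 * within + 0.07 * rs)
  # deuterated inner tails outscatter the hydrogenated LPS tails in D2O
  expect_lt(lay$sld[lay$name == "outer_tail"],
            lay$sld[lay$name == "inner_tail"])

  # empty surface: membrane layers collapse to pure solvent
  empty <- fsb_model(coverage = 0, materials = mats)
  pe <- build_slabs(empty, d2o)
  mem <- pe$layers$name %in%
    c("water_gap", "inner_head", "inner_tail", "outer_tail", "lps_core")
  expect_equal(pe$layers$sld[mem], rep(rs, sum(mem)))
})

test_that("protein layers extend the head region without touching the original", {
  m <- fsb_model()
  ml <- add_protein_layer(m, 90, 0.3)
  expect_null(m$protein)
  expect_equal(ml$protein$thickness, 90)
  p <- build_slabs(ml, contrast_condition(1, "up"))
  expect_true("protein" %in% p$layers$name)

  # null-layer property: thickness 0 or fraction 0 leaves reflectivity
  # unchanged under every contrast
  inst <- tiny_instrument()
  for (null_model in list(add_protein_layer(m, 0, 0.5),
                          add_protein_layer(m, 50, 0))) {
    for (ct in default_contrasts()) {
      c0 <- measured_curve(build_slabs(m, ct), inst, warn_roughness = FALSE)
      c1 <- measured_curve(build_slabs(null_model, ct), inst,
                           warn_roughness = FALSE)
      expect_equal(c1, c0, tolerance = 1e-12)
    }
  }
})

test_that("continuous SLD profiles broaden interfaces with erf steps", {
  # piecewise-constant at zero roughness
  p <- slab_profile(c(50, 30), c(4, 1), c(0, 0), 2.07, 6.38, 0)
  z <- seq(-20, 120, by = 1)
  prof <- sld_profile(p, z)
  expect_equal(prof[z < 0], rep(2.07, sum(z < 0)))
  expect_equal(prof[z > 0 & z < 50], rep(4, sum(z > 0 & z < 50)))
  expect_equal(prof[z > 50 & z < 80], rep(1, sum(z > 50 & z < 80)))
  expect_equal(prof[z > 80], rep(6.38, sum(z > 80)))

  # single rough interface: midpoint value at the interface, limits at inf
  p1 <- slab_profile(numeric(0), numeric(0), numeric(0), 2.07, 6.38,
                     backing_roughness = 5)
  expect_equal(sld_profile(p1, 0), (2.07 + 6.38) / 2)
  expect_equal(sld_profile(p1, c(-100, 100)), c(2.07, 6.38),
               tolerance = 1e-9)
  expect_error(sld_profile(p1, c(1, 0)), "monotone")
})

test_that("the H2O and D2O profiles carry the asymmetry signature", {
  m <- fsb_model()
  z <- seq(0, sum(membrane_window(m)) + 60, by = 0.25)
  win <- membrane_window(m)
  sub <- sum(m$substrate$thickness)

  # H2O contrast: the deuterated inner-tail region is the brightest part
  # of the membrane
  prof_h <- sld_profile(build_slabs(m, contrast_condition(0, "up")), z)
  zin <- z >= win[1] & z <= win[2]
  z_max <- z[zin][which.max(prof_h[zin])]
  lo_in <- sub + m$water_gap + m$t_inner_head
  expect_gte(z_max, lo_in)
  expect_lte(z_max, lo_in + m$t_inner_tail)

  # D2O contrast: the hydrogenated LPS-tail region is a local minimum
  # (lower than the flanking inner-tail and core regions)
  prof_d <- sld_profile(build_slabs(m, contrast_condition(1, "up")), z)
  lo_out <- lo_in + m$t_inner_tail
  hi_out <- lo_out + m$t_outer_tail
  v_out <- min(prof_d[z >= lo_out & z <= hi_out])
  expect_lt(v_out, prof_d[which.min(abs(z - (lo_out - 8)))])
  expect_lt(v_out, prof_d[which.min(abs(z - (hi_out + 12)))])
})
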