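test_that("generated series honor exact water bookkeeping", {
  gen <- generate_series(preset_scenario("gly_urea", noise_sd = 0))
  tt <- gen$truth$per_molality
  W <- 1 / 0.018015
  # claimed = spheres + interaction; N_e counts claimed water per mole
  m_tot <- 1 + tt$m
  expect_equal(tt$claimed, tt$N_e_true * m_tot, tolerance = 1e-12)
  expect_equal(tt$N_s_true * m_tot + tt$interaction_moles, tt$claimed,
               tolerance = 1e-12)
  expect_true(all(tt$claimed < W))
  # the realized epsilon of a sample decomposes into bulk + affected water
  s3 <- gen$series$samples[[3]]
  eps <- hdoshell:::sample_epsilon(s3, c(2200, 2750))
  tr <- gen$truth
  keep <- tr$bulk_eps$wavenumber >= 2200 & tr$bulk_eps$wavenumber <= 2750
  model <- ((W - tt$claimed[3]) * tr$bulk_eps$intensity +
            7 * 1 * tr$components$gly$eps$intensity +
            6 * tt$m[3] * tr$components$urea$eps$intensity +
            tt$interaction_moles[3] * tr$interaction_eps$intensity) / W
  expect_equal(eps$intensity, model[keep], tolerance = 1e-8)
})

test_that("identical scenario and seed give bit-identical series", {
  a <- generate_series(preset_scenario("single_urea", seed = 123))
  b <- generate_series(preset_scenario("single_urea", seed = 123))
  expect_identical(a$series$samples[[2]]$sample_spectrum$intensity,
                   b$series$samples[[2]]$sample_spectrum$intensity)
  c <- generate_series(preset_scenario("single_urea", seed = 124))
  expect_false(identical(a$series$samples[[2]]$sample_spectrum$intensity,
                         c$series$samples[[2]]$sample_spectrum$intensity))
})

test_that("impossible scenarios are refused", {
  urea <- solute_spec("urea", 0.06006, "osmolyte")
  scn <- generator_scenario(
    list(list(solute = urea, N_true = 12,
              band = list(center = 2520, fwhm = 150, eta = 0))),
    molalities = c(0, 2, 6))   # 72 mol claimed > 55.5 available
  expect_error(generate_series(scn), "exceeds the available")

  gly <- solute_spec("gly", 0.07507)
  scn2 <- generator_scenario(
    list(list(solute = gly, N_true = 2,
              band = list(center = 2530, fwhm = 120, eta = 0))),
    molalities = c(0, 0.5, 1),
    interaction = list(amount = function(m) -1.5 * m,
                       band = list(center = 2450, fwhm = 60, eta = 0)))
  expect_error(generate_series(scn2), "exceeds the component intensity")
  expect_error(generator_scenario(list(list(solute = gly, N_true = 2,
                                            molality = 1,
                                            band = list(center = 2500,
                                                        fwhm = 100))),
                                  molalities = 0:3), "varied")
})

test_that("presets cover the studied systems and stay solvable", {
  ps <- preset_scenarios()
  expect_true(all(c("single_gly", "single_nmg", "single_tmg", "single_urea",
                    "single_trpzip", "single_hewl",
                    "trpzip_tmg", "hewl_tmg", "trpzip_urea", "hewl_urea",
                    "gly_tmg", "nmg_tmg", "gly_urea", "nmg_urea",
                    "additive_gly_tmg") %in% names(ps)))
  expect_error(preset_scenario("nope"), "unknown preset")
  # every two-solute preset generates without scenario errors at its
  # default noise, and crossover presets change sign at the right molality
  for (nm in names(ps)) expect_silent(generate_series(preset_scenario(nm)))
  x <- vapply(preset_scenario("gly_tmg")$molalities,
              preset_scenario("gly_tmg")$interaction$amount, 0)
  m <- preset_scenario("gly_tmg")$molalities
  expect_true(all(x[m < 2.4] > 0) && all(x[m > 2.4] < 0))
  x2 <- vapply(preset_scenario("nmg_tmg")$molalities,
               preset_scenario("nmg_tmg")$interaction$amount, 0)
  m2 <- preset_scenario("nmg_tmg")$molalities
  expect_true(all(x2[m2 < 1] > 0) && all(x2[m2 > 1] < 0))
})
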