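test_that("isolate_hdo subtracts the reference and cancels solute bands", {
  s <- gauss_spectrum(2500, 150, kind = "absorbance")
  pair <- solution_sample(s, s)
  z <- isolate_hdo(pair)
  expect_lt(max(abs(z$intensity)), 1e-14)

  # sample = reference + known band -> band recovered exactly
  band <- pseudo_voigt(default_grid, 2505, 160, 0.15, 0.4)
  samp <- hdo_spectrum(default_grid, s$intensity + band,
                       kind = "absorbance", path_length_mm = 0.029)
  rec <- isolate_hdo(solution_sample(samp, s))
  keep <- default_grid >= 2200 & default_grid <= 2750
  expect_lt(max(abs(rec$intensity - band[keep])), 1e-10)

  # generator scenario: solute band at 2290 present in both members leaves
  # no residual in the difference
  gen <- generate_series(preset_scenario("single_gly", noise_sd = 0))
  hdo <- isolate_hdo(gen$series$samples[[5]])
  in_solute_band <- hdo$wavenumber >= 2270 & hdo$wavenumber <= 2310
  truth <- gen$truth
  # residual solute-band structure relative to the OD band maximum
  smooth_bg <- predict(stats::smooth.spline(hdo$wavenumber[!in_solute_band],
                                            hdo$intensity[!in_solute_band]),
                       hdo$wavenumber[in_solute_band])$y
  expect_lt(max(abs(hdo$intensity[in_solute_band] - smooth_bg)),
            0.001 * max(hdo$intensity))
})

test_that("path-length mismatch beyond 2% is refused", {
  s <- gauss_spectrum(kind = "absorbance")
  r <- s
  r$meta$path_length_mm <- 0.031
  expect_error(isolate_hdo(solution_sample(s, r)), "path length")
})

test_that("concentration derivative is exact for constructed series", {
  urea <- solute_spec("urea", 0.06006, "osmolyte")
  grid <- default_grid
  eb <- pseudo_voigt(grid, 2505, 160, 0.15, 10)
  slope <- pseudo_voigt(grid, 2520, 140, 0, 0.3) - 0.02 * eb
  mk_series <- function(f) {
    samples <- lapply(c(0, 0.5, 1, 1.5, 2), function(m) {
      d_dm <- 0.029 / 100
      # invert the molarity convention so eps(m) is exactly f(m)
      cw <- 1 / (1 + m * urea$molar_mass) / 0.018015
      samp <- hdo_spectrum(grid, f(m) * d_dm * cw, kind = "absorbance",
                           path_length_mm = 0.029)
      ref <- hdo_spectrum(grid, rep(0, length(grid)), kind = "absorbance",
                          path_length_mm = 0.029)
      solution_sample(samp, ref, list(urea), c(urea = m))
    })
    solution_series(samples, urea)
  }
  # identical spectra at all molalities -> zero derivative
  f0 <- fit_concentration_derivative(mk_series(function(m) eb), smooth_n = 1)
  expect_lt(max(abs(f0$derivative$intensity)), 1e-10)
  expect_equal(f0$bulk$intensity, eb[grid >= 2200 & grid <= 2750],
               tolerance = 1e-10)

  # exactly linear eps(m) -> slope recovered to 1e-9
  f1 <- fit_concentration_derivative(mk_series(function(m) eb + m * slope),
                                     smooth_n = 1)
  expect_lt(max(abs(f1$derivative$intensity -
                    slope[grid >= 2200 & grid <= 2750])), 1e-9)

  # quadratic curvature, quadratic fit -> slope at m = 0 within 1%
  curv <- pseudo_voigt(grid, 2480, 120, 0, 0.05)
  f2 <- fit_concentration_derivative(
    mk_series(function(m) eb + m * slope + m^2 * curv),
    fit_order = 2L, smooth_n = 1)
  expect_lt(max(abs(f2$derivative$intensity -
                    slope[grid >= 2200 & grid <= 2750])) /
            max(abs(slope)), 0.01)
  expect_error(fit_concentration_derivative(
    solution_series(mk_series(function(m) eb)$samples[1:2], urea)),
    "at least 3")
})

test_that("affected_spectrum implements eps_a = eps_b + deriv/(N M)", {
  eb <- gauss_spectrum(2505, 160)
  dv <- gauss_spectrum(2520, 140, height = 0.2)
  # zero derivative -> affected equals bulk for any N
  z <- dv; z$intensity <- rep(0, length(z$intensity))
  expect_equal(affected_spectrum(eb, z, 3)$intensity, eb$intensity)
  # N -> infinity limit approaches bulk
  big <- affected_spectrum(eb, dv, 1e12)
  expect_lt(max(abs(big$intensity - eb$intensity)), 1e-10)
  ea <- affected_spectrum(eb, dv, 5)
  expect_equal(ea$intensity,
               eb$intensity + dv$intensity / (5 * 0.018015))
})

test_that("estimate_N hits the constructed boundary case exactly", {
  # derivative = -N0 * M * eps_b: the solute removes bulk water exactly,
  # so the smallest admissible N is N0 with eps_a identically zero
  N0 <- 6.5
  eb <- gauss_spectrum(2505, 160, height = 10)
  dv <- eb
  dv$intensity <- -N0 * 0.018015 * eb$intensity
  est <- estimate_N(eb, dv)
  expect_equal(est$N, N0, tolerance = 1e-3)
  ea <- affected_spectrum(eb, dv, est$N)
  expect_lt(max(abs(ea$intensity)), 1e-3 * max(eb$intensity))
  expect_true(is.data.frame(est$trace))
  expect_true(any(est$trace$feasible))
})

test_that("noiseless pipeline recovers N_true and the affected band shape", {
  for (nm in c("urea", "tmg", "trpzip")) {
    gen <- generate_series(preset_scenario(paste0("single_", nm),
                                           noise_sd = 0))
    fit <- single_fit(nm)
    truth <- gen$truth$components[[1]]
    expect_lt(abs(fit$N / truth$N_true - 1), 0.02)
    tr <- resample(truth$eps, fit$affected_spectrum$wavenumber)
    rms <- sqrt(mean((fit$affected_spectrum$intensity - tr$intensity)^2))
    expect_lt(rms / max(tr$intensity), 0.01)
  }
})

test_that("N is scale-equivariant: intensity rescaling leaves N unchanged", {
  gen <- generate_series(preset_scenario("single_gly", noise_sd = 0))
  fit <- single_fit("gly")
  scaled <- gen$series
  for (i in seq_along(scaled$samples)) {
    scaled$samples[[i]]$sample_spectrum$intensity <-
      scaled$samples[[i]]$sample_spectrum$intensity * 3.7
    scaled$samples[[i]]$reference_spectrum$intensity <-
      scaled$samples[[i]]$reference_spectrum$intensity * 3.7
  }
  fit2 <- suppressWarnings(fit_affected_water(scaled))
  expect_equal(fit2$N, fit$N, tolerance = 1e-6)
  expect_equal(fit2$affected_spectrum$intensity,
               3.7 * fit$affected_spectrum$intensity, tolerance = 1e-6)
})

test_that("adding bulk-shaped signal to the derivative lowers estimated N", {
  eb <- gauss_spectrum(2505, 160, height = 10)
  dv <- gauss_spectrum(2520, 130, height = 0.5)
  dv$intensity <- dv$intensity - 0.4 * eb$intensity
  Ns <- vapply(c(0, 0.05, 0.1), function(extra) {
    d2 <- dv
    d2$intensity <- dv$intensity + extra * eb$intensity
    estimate_N(eb, d2)$N
  }, 0)
  expect_true(all(diff(Ns) < 0))
})

test_that("affected_water fit object exposes the standard methods", {
  fit <- single_fit("urea")
  expect_s3_class(fit, "affected_water")
  expect_named(coef(fit), "N")
  expect_output(print(fit), "Affected-water fit")
  expect_output(print(summary(fit)), "gravity center")
  expect_true(is.matrix(residuals(fit)))
  pred0 <- predict(fit, molality = 0)
  expect_equal(pred0$intensity, fit$bulk_spectrum$intensity)
})
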