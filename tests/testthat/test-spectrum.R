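test_that("two-column text round-trips losslessly and normalizes orientation", {
  s <- gauss_spectrum(2505, 160)
  p <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, p)
  r <- read_spectrum(p)
  expect_equal(r$wavenumber, s$wavenumber, tolerance = 1e-9)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-9)

  # descending input grid is reversed on construction
  d <- hdo_spectrum(rev(s$wavenumber), rev(s$intensity))
  expect_equal(d$wavenumber, s$wavenumber)
  expect_equal(d$intensity, s$intensity)

  # tiny hand-written file
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2400 0.1", "2410 0.3", "2420 0.1", "2430 0.2",
               "2440 0.25", "2450 0.2", "2460 0.15", "2470 0.1"), p2)
  r2 <- read_spectrum(p2)
  expect_length(r2$wavenumber, 8)
  expect_equal(r2$intensity[2], 0.3)
})

test_that("JCAMP-DX writer/reader round-trip is exact to 1e-9", {
  s <- gauss_spectrum(2480, 140, height = 0.37)
  p <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(s, p, "jcamp_dx")
  r <- read_spectrum(p)   # format auto-detected from ## header
  expect_equal(r$wavenumber, s$wavenumber, tolerance = 1e-9)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-9)
  expect_equal(r$meta$path_length_mm, 0.029)
})

test_that("malformed files raise parse errors naming the line", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2400 0.1", "2410 xyz", "2420 0.1"), p)
  expect_error(read_spectrum(p), "line 2")
  writeLines(c("2400 0.1", "2400 0.2", "2410 0.1", "2420 0.1",
               "2430 0.1", "2440 0.1", "2450 0.1", "2460 0.1"), p)
  expect_error(read_spectrum(p), "monotone")
})

test_that("resampling is exact on its own grid and conserves band area", {
  s <- gauss_spectrum(2500, 120)
  expect_equal(resample(s, s$wavenumber)$intensity, s$intensity)

  # linear ramp: midpoints are exact for both interpolants
  ramp <- hdo_spectrum(seq(2400, 2600, 20), seq(0, 1, length.out = 11),
                       kind = "molar_absorptivity")
  mid <- seq(2410, 2590, 20)
  expect_equal(resample(ramp, mid, "linear")$intensity,
               seq(0.05, 0.95, 0.1), tolerance = 1e-12)
  expect_equal(resample(ramp, mid)$intensity,
               seq(0.05, 0.95, 0.1), tolerance = 1e-12)

  # area conservation under 4x refinement, against quadrature on the fine grid
  fine <- seq(min(s$wavenumber), max(s$wavenumber), by = 0.25)
  r <- resample(s, fine)
  expect_lt(abs(trapz(r$wavenumber, r$intensity) /
                trapz(s$wavenumber, s$intensity) - 1), 1e-3)
  expect_error(resample(s, c(2000, 2500)), "beyond")
})

test_that("unit conversion follows Beer-Lambert and inverts exactly", {
  a <- gauss_spectrum(2500, 150, height = 0.5, kind = "absorbance")
  e <- to_molar_absorptivity(a, water_molarity = 55.3)
  expect_equal(e$intensity, a$intensity / (0.029 / 100 * 55.3))
  # doubling the path length halves epsilon for fixed absorbance
  a2 <- a; a2$meta$path_length_mm <- 0.058
  expect_equal(to_molar_absorptivity(a2, 55.3)$intensity, e$intensity / 2)
  # round trip
  back <- to_absorbance(e, 55.3)
  expect_equal(back$intensity, a$intensity, tolerance = 1e-12)
  # zeros stay zeros
  z <- a; z$intensity <- rep(0, length(z$intensity))
  expect_equal(max(abs(to_molar_absorptivity(z, 55.3)$intensity)), 0)
  # metadata guard
  noa <- a; noa$meta$path_length_mm <- NA_real_
  expect_error(to_molar_absorptivity(noa, 55.3), "path_length")
})

test_that("baseline subtraction recovers a tilted band and kills pure lines", {
  grid <- default_grid
  line <- hdo_spectrum(grid, 0.2 + 3e-4 * (grid - 2150))
  anchors <- list(c(2150, 2200), c(2740, 2800))
  out <- subtract_baseline(line, anchors)
  expect_lt(max(abs(out$intensity)), 1e-12)

  band <- pseudo_voigt(grid, 2500, 130, 0, 1)
  tilted <- hdo_spectrum(grid, band + 0.1 + 2e-4 * (grid - 2150))
  rec <- subtract_baseline(tilted, anchors)
  expect_lt(sqrt(mean((rec$intensity - band)^2)), 0.005)

  z <- hdo_spectrum(grid, rep(0, length(grid)))
  expect_equal(max(abs(subtract_baseline(z, anchors)$intensity)), 0)
  expect_error(subtract_baseline(line, list(c(1000, 1100))), "anchor window")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(hdo_spectrum(1:7, 1:7), "at least 8")
  expect_error(hdo_spectrum(1:8, 1:9), "equal length")
  expect_error(hdo_spectrum(c(1:4, 4, 5:7), rep(1, 8)), "monotone")
  expect_error(hdo_spectrum(1:8, c(1:7, NA)), "non-finite")
})
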