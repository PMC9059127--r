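test_that("np_transform arithmetic and composition bookkeeping hold", {
  expect_equal(np_transform(7, 0), 7)
  expect_equal(np_transform(2, 4), 10)
  expect_error(np_transform(2, -1), "non-negative")
  # (n_m N_m + n_o N_o)(beta + 1) with beta = n_o/n_m equals N_m + beta N_o
  N_m <- 7; N_o <- 12; beta <- 2.5
  n_m <- 1 / (1 + beta); n_o <- beta / (1 + beta)
  expect_equal(np_transform(n_m * N_m + n_o * N_o, beta),
               N_m + beta * N_o, tolerance = 1e-12)
})

test_that("synthetic_affected mixes components by N-weighted composition", {
  fit_m <- single_fit("gly")
  fit_o <- single_fit("tmg")
  # single-component limits return the component exactly
  s0 <- synthetic_affected(fit_m, fit_o, 1, 0)
  expect_equal(s0$N_s, fit_m$N)
  expect_equal(s0$spectrum$intensity, fit_m$affected_spectrum$intensity)
  # identical components: any composition returns the component
  sid <- synthetic_affected(fit_m, fit_m, 0.3, 0.7)
  expect_equal(sid$spectrum$intensity, fit_m$affected_spectrum$intensity,
               tolerance = 1e-12)
  # two distinct Gaussians, equal n and N: arithmetic-mean spectrum whose
  # gravity center is the mean of the component centers
  mk <- function(center) {
    f <- fit_m
    f$N <- 5
    f$affected_spectrum <- gauss_spectrum(center, 100, height = 1)
    f
  }
  mix <- synthetic_affected(mk(2420), mk(2580), 0.5, 0.5)
  expect_equal(mix$N_s, 5)
  expect_equal(mix$spectrum$intensity,
               (mk(2420)$affected_spectrum$intensity +
                mk(2580)$affected_spectrum$intensity) / 2)
  expect_equal(gravity_center(mix$spectrum), 2500, tolerance = 0.01)
  expect_error(synthetic_affected(fit_m, fit_o, 0.6, 0.6), "sum to 1")
})

test_that("experimental_affected reduces to the single-solute result at m_o = 0", {
  fit_m <- single_fit("gly")
  gen <- generate_series(preset_scenario("single_gly", noise_sd = 0))
  res <- experimental_affected(gen$series$samples[[3]],
                               fit_m$bulk_spectrum)
  expect_lt(abs(res$N_e / fit_m$N - 1), 0.005)
  expect_lt(max(abs(res$spectrum$intensity -
                    fit_m$affected_spectrum$intensity)) /
            max(fit_m$affected_spectrum$intensity), 0.01)
})

test_that("additive two-solute scenario gives N_e = n_m N_m + n_o N_o", {
  fit_m <- single_fit("gly")
  fit_o <- single_fit("tmg")
  gen <- generate_series(preset_scenario("additive_gly_tmg", noise_sd = 0))
  for (i in c(1, 3, 5)) {
    fd <- fit_double_affected(gen$series$samples[[i]], fit_m, fit_o,
                              mc_draws = 0)
    expect_lt(abs(fd$N_e / fd$N_s - 1), 0.01)
    expect_equal(fd$n_m + fd$n_o, 1)
  }
})

test_that("shared-overlap scenario recovers the constructed interaction water", {
  fit_m <- single_fit("gly")
  fit_o <- single_fit("urea")
  gen <- generate_series(preset_scenario("gly_urea", noise_sd = 0))
  truth <- gen$truth
  for (i in c(2, 4)) {
    fd <- fit_double_affected(gen$series$samples[[i]], fit_m, fit_o,
                              mc_draws = 0)
    expect_equal(fd$regime, "shared_overlap")
    tt <- truth$per_molality[i, ]
    expect_lt(abs(fd$N_double / tt$N_double_true - 1), 0.05)
    tr <- resample(truth$interaction_eps, fd$double_spectrum$wavenumber)
    rms <- sqrt(mean((fd$double_spectrum$intensity - tr$intensity)^2))
    expect_lt(rms / max(tr$intensity), 0.03)
  }
})

test_that("cross-linking scenario is detected with the constructed amount", {
  fit_m <- single_fit("nmg")
  fit_o <- single_fit("tmg")
  gen <- generate_series(preset_scenario("nmg_tmg", noise_sd = 0))
  truth <- gen$truth$per_molality
  i <- 2   # below the crossover molality
  fd <- fit_double_affected(gen$series$samples[[i]], fit_m, fit_o,
                            mc_draws = 0)
  expect_equal(fd$regime, "cross_linking")
  expect_gt(fd$N_double, 0)
  expect_lt(abs(fd$N_double / truth$N_double_true[i] - 1), 0.05)
  tr <- resample(gen$truth$interaction_eps, fd$double_spectrum$wavenumber)
  expect_lt(sqrt(mean((fd$double_spectrum$intensity - tr$intensity)^2)) /
            max(tr$intensity), 0.03)
})

test_that("double_affected sign convention round-trips exactly", {
  # reconstruction N_s eps_s + N_double * eps_double == N_e eps_e both for
  # shared (negated) and cross-linking (unnegated) regimes
  for (preset in c("gly_urea", "nmg_tmg")) {
    fit_m <- single_fit(strsplit(preset, "_")[[1]][1])
    fit_o <- single_fit(strsplit(preset, "_")[[1]][2])
    gen <- generate_series(preset_scenario(preset, noise_sd = 0))
    fd <- fit_double_affected(gen$series$samples[[2]], fit_m, fit_o,
                              mc_draws = 0)
    recon <- fd$N_s * fd$synthetic_spectrum$intensity +
      fd$N_double * fd$double_spectrum$intensity
    expect_lt(max(abs(recon - fd$N_e * fd$experimental_spectrum$intensity)),
              1e-9)
  }
})

test_that("no-interaction data yield the additive regime under uncertainty", {
  fit_m <- single_fit("gly")
  fit_o <- single_fit("tmg")
  gen <- generate_series(preset_scenario("additive_gly_tmg", noise_sd = 0))
  fd <- fit_double_affected(gen$series$samples[[3]], fit_m, fit_o,
                            mc_draws = 0)
  # noiseless additive: |N_double| far below even the minimal floor scale
  expect_lt(abs(fd$N_double), 0.005 * fd$N_s)
  expect_equal(double_affected(
    list(spectrum = fd$experimental_spectrum, N_e = fd$N_s),
    list(spectrum = fd$experimental_spectrum, N_s = fd$N_s),
    uncertainty_floor = 1e-9)$regime, "additive")
})

test_that("titration_profile tabulates one row per osmolyte molality", {
  pr <- preset_profile("gly_urea", "gly", "urea")
  prof <- pr$profile
  scn <- preset_scenario("gly_urea")
  expect_equal(nrow(prof), length(scn$molalities))
  expect_equal(prof$m_o, scn$molalities)
  expect_named(prof, c("m_o", "beta", "N_e", "N_s", "N_pe", "N_ps",
                       "regime", "nu_g_double"))
  expect_equal(prof$N_pe, prof$N_e * (prof$beta + 1))
  # regime agrees with the sign of N_pe - N_ps wherever it is significant
  sig <- prof$regime != "additive"
  expect_true(all((prof$N_pe < prof$N_ps)[sig] ==
                  (prof$regime == "shared_overlap")[sig]))
})
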