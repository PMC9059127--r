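# shared fixtures: everything is generated in code at test time

default_grid <- seq(2150, 2800, by = 1)

gauss_spectrum <- function(center = 2500, fwhm = 150, height = 1,
                           grid = default_grid, kind = "molar_absorptivity",
                           path_length_mm = 0.029) {
  hdo_spectrum(grid, pseudo_voigt(grid, center, fwhm, 0, height),
               kind = kind, path_length_mm = path_length_mm)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# expensive fits are shared across test files within one run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

single_fit <- function(name, noise_sd = 0) {
  cached(paste0("fit_", name, "_", noise_sd), suppressWarnings(
    fit_affected_water(
      generate_series(preset_scenario(paste0("single_", name),
                                      noise_sd = noise_sd))$series)))
}

preset_profile <- function(name, fit_m_name, fit_o_name, mc_draws = 100) {
  cached(paste0("prof_", name), {
    gen <- generate_series(preset_scenario(name))
    prof <- suppressWarnings(titration_profile(
      gen$series, single_fit(fit_m_name), single_fit(fit_o_name),
      mc_draws = mc_draws))
    list(profile = prof, truth = gen$truth)
  })
}
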