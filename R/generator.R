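#' Define a synthetic titration scenario
#'
#' Forward model for HDO titration series with known ground truth, emulating
#' the experimental design of osmolyte/biomolecule hydration studies: a
#' biomolecule (or unfolded-protein model) at constant molality, an osmolyte
#' titrated over a molality series, HDO at a fixed D2O mass fraction of total
#' water, and matched H2O reference solutions. Every sample is composed in
#' molar-absorptivity space as bulk water minus the water claimed by the
#' solutes plus the N-weighted affected components, plus (signed) interaction
#' water, then converted to absorbance and overlaid on a common background of
#' baseline drift and solute bands, with seeded white noise.
#'
#' @param components list of component definitions, each a list with fields
#'   `solute` (a [solute_spec()]), `N_true` (mol water per mol solute),
#'   `band` (list `center`, `fwhm`, `eta`), optional `rel_area` (band area
#'   relative to the bulk band, default 1) and `molality` (fixed molality for
#'   constant solutes; `NA` marks the varied solute — exactly one).
#' @param molalities molalities of the varied solute, non-negative increasing.
#' @param interaction `NULL`, or a list with `amount` (function of the varied
#'   molality returning signed moles of interaction water per kg of water:
#'   positive = cross-linking water drawn from the bulk, negative = water
#'   shared between the hydration spheres), `band` and optional `rel_area`.
#' @param bulk_band bulk-HDO band parameters; the default pseudo-Voigt
#'   (2505 cm^-1, FWHM 160 cm^-1, 15% Lorentzian) maps, under the default
#'   distance calibration, to a most-probable O...O distance of 2.83 A.
#' @param noise_sd white-noise standard deviation as a fraction of the
#'   pure-water HDO absorbance band maximum; the default 0.05% is
#'   representative of a few-hundred-scan FTIR average.
#' @param seed RNG seed used by [generate_series()].
#' @param grid wavenumber grid, cm^-1.
#' @param d2o_mass_fraction,path_length_mm,temperature_C,density_kg_dm3
#'   acquisition metadata shared by all samples.
#' @param molar_mass_water kg mol^-1.
#' @return An object of class `generator_scenario`.
#' @seealso [preset_scenario()] for ready-made systems.
#' @export
generator_scenario <- function(components, molalities, interaction = NULL,
                               bulk_band = list(center = 2505, fwhm = 160,
                                                eta = 0.15, height = 10),
                               noise_sd = 5e-4, seed = 20220420,
                               grid = seq(2150, 2800, by = 1),
                               d2o_mass_fraction = 0.04,
                               path_length_mm = 0.029,
                               temperature_C = 25,
                               density_kg_dm3 = 1.0,
                               molar_mass_water = 0.018015) {
  stopifnot(length(components) >= 1, all(molalities >= 0),
            !is.unsorted(molalities, strictly = TRUE), noise_sd >= 0)
  varied <- which(vapply(components, function(co) is.na(co$molality %||% NA),
                         TRUE))
  if (length(varied) != 1L)
    stop("exactly one component must have molality = NA (the varied solute)",
         call. = FALSE)
  for (co in components) stopifnot(co$N_true > 0)
  structure(list(components = components, varied = varied,
                 molalities = molalities, interaction = interaction,
                 bulk_band = bulk_band, noise_sd = noise_sd, seed = seed,
                 grid = grid, d2o_mass_fraction = d2o_mass_fraction,
                 path_length_mm = path_length_mm,
                 temperature_C = temperature_C,
                 density_kg_dm3 = density_kg_dm3,
                 molar_mass_water = molar_mass_water),
            class = "generator_scenario")
}

#' @export
print.generator_scenario <- function(x, ...) {
  nm <- vapply(x$components, function(co) co$solute$name, "")
  cat(sprintf("<generator_scenario> %s; varied: %s; %d molalities; noise %.2g%%\n",
              paste(nm, collapse = " + "), nm[x$varied],
              length(x$molalities), 100 * x$noise_sd))
  invisible(x)
}

# pseudo-Voigt band scaled to rel_area x the bulk band area
scenario_band <- function(grid, band, rel_area, bulk_area) {
  y <- pseudo_voigt(grid, band$center, band$fwhm, band$eta %||% 0)
  y * rel_area * bulk_area / trapz(grid, y)
}

#' Generate a titration series with ground truth
#'
#' Realizes a [generator_scenario()] into a [solution_series()] of
#' sample/reference spectrum pairs plus the ground truth needed to validate
#' every analysis stage: the bulk and component molar-absorptivity spectra,
#' the interaction-water contour, and the expected affected counts per
#' molality. Water bookkeeping is exact: bulk + affected + interaction water
#' moles sum to the total water per kg. Identical scenario and seed give
#' bit-identical output.
#'
#' @param scn a `generator_scenario`.
#' @return List with `series` (a [solution_series()]) and `truth` (list:
#'   `bulk_eps`, per-component `components` with `N_true` and `eps`,
#'   `interaction_eps`, `per_molality` data frame with columns `m`,
#'   `interaction_moles`, `claimed`, `N_e_true`, `N_s_true`,
#'   `N_double_true`, `regime_true`, and `noise_sd_abs`).
#' @export
generate_series <- function(scn) {
  stopifnot(inherits(scn, "generator_scenario"))
  grid <- scn$grid
  W <- 1 / scn$molar_mass_water
  bulk_eps <- pseudo_voigt(grid, scn$bulk_band$center, scn$bulk_band$fwhm,
                           scn$bulk_band$eta, scn$bulk_band$height)
  bulk_area <- trapz(grid, bulk_eps)
  comp_eps <- lapply(scn$components, function(co)
    scenario_band(grid, co$band, co$rel_area %||% 1, bulk_area))
  int_eps <- if (!is.null(scn$interaction))
    scenario_band(grid, scn$interaction$band,
                  scn$interaction$rel_area %||% 1, bulk_area)
  solutes <- lapply(scn$components, `[[`, "solute")
  names(comp_eps) <- vapply(solutes, `[[`, "", "name")
  d_dm <- scn$path_length_mm / 100
  # background identical in HDO and reference solutions: baseline drift plus
  # one weak solute band per component, proportional to its molality
  background <- function(mols) {
    b <- 0.05 + 2e-5 * (grid - min(grid))
    for (i in seq_along(scn$components))
      b <- b + mols[i] * pseudo_voigt(grid, 2290, 50, 0.3, 0.03)
    b
  }
  # absorbance noise scale: fraction of the pure-water HDO band maximum
  c_w0 <- scn$density_kg_dm3 / scn$molar_mass_water
  noise_abs <- scn$noise_sd * max(bulk_eps) * d_dm * c_w0

  mk_sample <- function(m) {
    mols <- vapply(seq_along(scn$components), function(i)
      if (i == scn$varied) m else scn$components[[i]]$molality, 0)
    X <- if (!is.null(scn$interaction)) scn$interaction$amount(m) else 0
    claimed <- sum(vapply(seq_along(mols), function(i)
      scn$components[[i]]$N_true * mols[i], 0)) + X
    if (claimed > 0.95 * W)
      stop(sprintf(
        "scenario error: %.1f mol of water claimed per kg at m = %g exceeds the available %.1f",
        claimed, m, W), call. = FALSE)
    affected <- rep(0, length(grid))
    for (i in seq_along(mols))
      affected <- affected + scn$components[[i]]$N_true * mols[i] * comp_eps[[i]]
    if (!is.null(int_eps)) affected <- affected + X * int_eps
    if (min(affected) < -1e-9 * max(abs(affected)))
      stop(sprintf(
        "scenario error: shared interaction water exceeds the component intensity at m = %g",
        m), call. = FALSE)
    eps_model <- ((W - claimed) * bulk_eps + affected) / W
    # water molarity of this sample under the shared density convention
    solute_mass <- sum(vapply(seq_along(mols), function(i)
      mols[i] * scn$components[[i]]$solute$molar_mass, 0))
    c_w <- scn$density_kg_dm3 / (1 + solute_mass) / scn$molar_mass_water
    A_hdo <- eps_model * d_dm * c_w
    B <- background(mols)
    meta <- list(path_length_mm = scn$path_length_mm,
                 temperature_C = scn$temperature_C)
    samp <- hdo_spectrum(grid,
                         B + A_hdo + stats::rnorm(length(grid), 0, noise_abs),
                         path_length_mm = scn$path_length_mm,
                         temperature_C = scn$temperature_C,
                         label = sprintf("HDO m=%.4g", m))
    ref <- hdo_spectrum(grid,
                        B + stats::rnorm(length(grid), 0, noise_abs),
                        path_length_mm = scn$path_length_mm,
                        temperature_C = scn$temperature_C,
                        label = sprintf("H2O m=%.4g", m))
    molal <- stats::setNames(mols, names(comp_eps))
    solution_sample(samp, ref, solutes = solutes,
                    molalities = molal[molal > 0 | seq_along(molal) == scn$varied],
                    d2o_mass_fraction = scn$d2o_mass_fraction)
  }

  samples <- with_seed(scn$seed, function()
    lapply(scn$molalities, mk_sample))
  constant <- if (length(scn$components) > 1L)
    solutes[-scn$varied][[1]] else NULL
  series <- solution_series(samples, varied_solute = solutes[[scn$varied]],
                            constant_solute = constant)

  mk_spec <- function(y, lab) hdo_spectrum(grid, y, kind = "molar_absorptivity",
                                           temperature_C = scn$temperature_C,
                                           label = lab)
  per_m <- do.call(rbind, lapply(scn$molalities, function(m) {
    mols <- vapply(seq_along(scn$components), function(i)
      if (i == scn$varied) m else scn$components[[i]]$molality, 0)
    X <- if (!is.null(scn$interaction)) scn$interaction$amount(m) else 0
    sphere <- sum(vapply(seq_along(mols), function(i)
      scn$components[[i]]$N_true * mols[i], 0))
    m_tot <- sum(mols)
    data.frame(m = m, interaction_moles = X, claimed = sphere + X,
               N_e_true = if (m_tot > 0) (sphere + X) / m_tot else NA_real_,
               N_s_true = if (m_tot > 0) sphere / m_tot else NA_real_,
               N_double_true = if (m_tot > 0) X / m_tot else NA_real_,
               regime_true = if (X > 1e-12) "cross_linking"
                             else if (X < -1e-12) "shared_overlap"
                             else "additive")
  }))
  truth <- list(
    bulk_eps = mk_spec(bulk_eps, "bulk HDO (truth)"),
    components = lapply(seq_along(scn$components), function(i)
      list(solute = solutes[[i]], N_true = scn$components[[i]]$N_true,
           eps = mk_spec(comp_eps[[i]],
                         sprintf("%s affected (truth)", solutes[[i]]$name)))),
    interaction_eps = if (!is.null(int_eps))
      mk_spec(int_eps, "interaction water (truth)"),
    per_molality = per_m,
    noise_sd_abs = noise_abs,
    seed = scn$seed)
  names(truth$components) <- names(comp_eps)
  list(series = series, truth = truth)
}
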