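#' Describe a solute
#'
#' @param name identifier, e.g. `"urea"`.
#' @param molar_mass molar mass in kg mol^-1.
#' @param role `"biomolecule_or_model"` or `"osmolyte"`.
#' @return An object of class `solute_spec`.
#' @examples
#' urea <- solute_spec("urea", 0.06006, "osmolyte")
#' @export
solute_spec <- function(name, molar_mass,
                        role = c("biomolecule_or_model", "osmolyte")) {
  role <- match.arg(role)
  stopifnot(is.character(name), nzchar(name), molar_mass > 0)
  structure(list(name = name, molar_mass = molar_mass, role = role),
            class = "solute_spec")
}

#' @export
print.solute_spec <- function(x, ...) {
  cat(sprintf("<solute_spec> %s (%s), M = %.4g kg/mol\n",
              x$name, x$role, x$molar_mass))
  invisible(x)
}

#' Pair an HDO sample spectrum with its H2O reference
#'
#' A sample holds the HDO-series spectrum, the matched H2O reference spectrum
#' (same solutes, equal molar water), the solute molalities and the D2O mass
#' fraction of total water. The reference subtraction in [isolate_hdo()]
#' removes solute and H2O bands and leaves the OD contour of HDO.
#'
#' @param sample_spectrum `hdo_spectrum` of the HDO-containing solution.
#' @param reference_spectrum `hdo_spectrum` of the matched H2O solution.
#' @param solutes list of [solute_spec()] objects.
#' @param molalities named numeric vector, mol (kg water)^-1, names matching
#'   solute names. May be empty for a pure-water baseline pair.
#' @param d2o_mass_fraction D2O as a fraction of total water mass, in (0, 0.1].
#' @return An object of class `solution_sample`.
#' @export
solution_sample <- function(sample_spectrum, reference_spectrum,
                            solutes = list(), molalities = numeric(0),
                            d2o_mass_fraction = 0.04) {
  assert_spectrum(sample_spectrum)
  assert_spectrum(reference_spectrum)
  stopifnot(d2o_mass_fraction > 0, d2o_mass_fraction <= 0.1)
  if (length(molalities)) {
    if (is.null(names(molalities)) ||
        !all(names(molalities) %in% vapply(solutes, `[[`, "", "name")))
      stop("molalities must be named after the given solutes", call. = FALSE)
    if (any(molalities < 0)) stop("negative molality", call. = FALSE)
  }
  structure(list(sample_spectrum = sample_spectrum,
                 reference_spectrum = reference_spectrum,
                 solutes = solutes, molalities = molalities,
                 d2o_mass_fraction = d2o_mass_fraction),
            class = "solution_sample")
}

sample_molality <- function(sample, solute_name) {
  if (!solute_name %in% names(sample$molalities)) return(0)
  unname(sample$molalities[[solute_name]])
}

total_molality <- function(sample) {
  if (!length(sample$molalities)) return(0)
  sum(sample$molalities)
}

#' Molar concentration of water in a solution sample
#'
#' Converts the molality bookkeeping (per kg of total water, D2O included) to
#' moles of water per dm^3 of solution, assuming a solution density
#' (default 1.00 kg dm^-3; the paper's dilute aqueous regime).
#'
#' @param sample a `solution_sample`.
#' @param density_kg_dm3 solution density.
#' @param molar_mass_water molar mass of water, kg mol^-1.
#' @return mol dm^-3 of water.
#' @export
water_molarity <- function(sample, density_kg_dm3 = 1.0,
                           molar_mass_water = 0.018015) {
  solute_mass <- 0
  for (s in sample$solutes)
    solute_mass <- solute_mass +
      sample_molality(sample, s$name) * s$molar_mass
  water_mass_fraction <- 1 / (1 + solute_mass)   # per kg water basis
  density_kg_dm3 * water_mass_fraction / molar_mass_water
}

#' Assemble a titration series
#'
#' An ordered set of sample/reference pairs sharing a constant solute
#' (optional) while a varied solute is titrated in strictly increasing
#' molality.
#'
#' @param samples list of [solution_sample()] objects.
#' @param varied_solute the titrated [solute_spec()].
#' @param constant_solute a [solute_spec()] held at fixed molality, or `NULL`.
#' @return An object of class `solution_series`.
#' @export
solution_series <- function(samples, varied_solute, constant_solute = NULL) {
  stopifnot(length(samples) >= 1)
  mv <- vapply(samples, sample_molality, 0, solute_name = varied_solute$name)
  if (any(diff(mv) <= 0))
    stop("varied-solute molality must be strictly increasing across samples",
         call. = FALSE)
  if (!is.null(constant_solute)) {
    mc <- vapply(samples, sample_molality, 0,
                 solute_name = constant_solute$name)
    if (diff(range(mc)) > 0.01 * max(mc))
      stop("constant-solute molality varies by more than 1% across samples",
           call. = FALSE)
  }
  structure(list(samples = samples, varied_solute = varied_solute,
                 constant_solute = constant_solute),
            class = "solution_series")
}

#' @export
print.solution_series <- function(x, ...) {
  mv <- vapply(x$samples, sample_molality, 0, solute_name = x$varied_solute$name)
  cat(sprintf("<solution_series> %d samples, %s titrated %.3g-%.3g mol/kg",
              length(x$samples), x$varied_solute$name, min(mv), max(mv)))
  if (!is.null(x$constant_solute))
    cat(sprintf(", %s constant at %.3g mol/kg",
                x$constant_solute$name,
                sample_molality(x$samples[[1]], x$constant_solute$name)))
  cat("\n")
  invisible(x)
}

varied_molalities <- function(series) {
  vapply(series$samples, sample_molality, 0,
         solute_name = series$varied_solute$name)
}
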