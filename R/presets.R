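#' Solutes used by the preset scenarios
#'
#' Glycine (GLY) and N-methylglycine (NMG) as minimal models of
#' unfolded-protein fragments; the trpzip-1 beta-hairpin peptide and hen egg
#' white lysozyme (hewl) as folded biomacromolecules; trimethylglycine (TMG,
#' betaine) as a stabilizing and urea as a destabilizing osmolyte.
#'
#' @return Named list of [solute_spec()] objects.
#' @export
preset_solutes <- function() {
  list(
    gly    = solute_spec("gly",    0.07507, "biomolecule_or_model"),
    nmg    = solute_spec("nmg",    0.08909, "biomolecule_or_model"),
    trpzip = solute_spec("trpzip", 1.5787,  "biomolecule_or_model"),
    hewl   = solute_spec("hewl",   14.3,    "biomolecule_or_model"),
    tmg    = solute_spec("tmg",    0.11715, "osmolyte"),
    urea   = solute_spec("urea",   0.06006, "osmolyte"))
}

# affected-water band shapes and affected numbers used by every preset.
# Component bands are Gaussian (eta = 0); the interaction bands are
# red-shifted for the stabilizer (stronger hydrogen bonds) and blue-shifted
# for the destabilizer (weaker hydrogen bonds).
preset_component <- function(name, molality = NA_real_) {
  tab <- list(
    gly    = list(N_true = 7,   band = list(center = 2530, fwhm = 140, eta = 0), rel_area = 1.10),
    nmg    = list(N_true = 9,   band = list(center = 2495, fwhm = 135, eta = 0), rel_area = 1.10),
    trpzip = list(N_true = 150, band = list(center = 2520, fwhm = 150, eta = 0), rel_area = 1.05),
    hewl   = list(N_true = 900, band = list(center = 2525, fwhm = 150, eta = 0), rel_area = 1.05),
    tmg    = list(N_true = 12,  band = list(center = 2480, fwhm = 140, eta = 0), rel_area = 1.15),
    urea   = list(N_true = 6,   band = list(center = 2520, fwhm = 150, eta = 0), rel_area = 1.00))
  co <- tab[[name]]
  co$solute <- preset_solutes()[[name]]
  co$molality <- molality
  co
}

# shared-water amount: a fraction of the smaller hydration sphere, tapering
# with osmolyte molality (saturation of the contact surface)
shared_amount <- function(N_m, m_m, N_o, frac, K) {
  function(m_o) -frac * pmin(N_m * m_m, N_o * m_o) / (1 + m_o / K)
}

# signed cross-linking/shared amount: positive (cross-linking water) below
# the crossover molality xc, negative (shared water) above, bounded at high
# molality
crossover_amount <- function(a, xc) {
  function(m_o) a * m_o * (1 - m_o / xc) / (1 + (m_o / xc)^2)
}

#' Ready-made generator scenarios
#'
#' Presets emulating the studied systems. Single-solute presets
#' (`single_gly`, `single_nmg`, `single_trpzip`, `single_hewl`, `single_tmg`,
#' `single_urea`) titrate one solute for affected-number determination.
#' Two-solute presets hold the biomolecule or model molecule at its
#' experimental molality (1 mol/kg for GLY and NMG, 0.035 for trpzip-1, 0.008
#' for hewl) and titrate the osmolyte:
#' the four biomacromolecule systems (`trpzip_tmg`, `hewl_tmg`,
#' `trpzip_urea`, `hewl_urea`) and the model+urea systems (`gly_urea`,
#' `nmg_urea`) share hydration-sphere water at every molality; the model+TMG
#' systems (`gly_tmg`, `nmg_tmg`) cross-link extra water below a crossover
#' molality (2.4 and 1.0 mol/kg respectively) and share water above it.
#' `additive_gly_tmg` is an interaction-free control.
#'
#' @param name preset name (see above).
#' @param noise_sd override the default noise level (0.05% of the bulk band
#'   maximum); use 0 for noiseless series.
#' @param seed override the default RNG seed.
#' @return A [generator_scenario()].
#' @examples
#' names(preset_scenarios())
#' scn <- preset_scenario("single_urea", noise_sd = 0)
#' @export
preset_scenario <- function(name, noise_sd = NULL, seed = NULL) {
  presets <- preset_scenarios()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; see names(preset_scenarios())",
         call. = FALSE)
  scn <- presets[[name]]
  if (!is.null(noise_sd)) scn$noise_sd <- noise_sd
  if (!is.null(seed)) scn$seed <- seed
  scn
}

#' @rdname preset_scenario
#' @export
preset_scenarios <- function() {
  single <- function(name, molalities)
    generator_scenario(list(preset_component(name)), molalities)
  pair <- function(m_name, m_mol, o_name, molalities, interaction,
                   int_band, int_rel = 1) {
    generator_scenario(
      components = list(preset_component(m_name, m_mol),
                        preset_component(o_name)),
      molalities = molalities,
      interaction = if (!is.null(interaction))
        list(amount = interaction, band = int_band, rel_area = int_rel))
  }
  small_m <- c(0, 0.5, 1, 1.5, 2)
  strong_band <- list(center = 2450, fwhm = 110, eta = 0)  # TMG-like, ~2.78 A
  weak_band   <- list(center = 2560, fwhm = 130, eta = 0)  # urea-like, ~2.88 A
  tmg_m  <- c(0.5, 1.0, 1.5, 2.0, 2.5, 2.93)
  urea_m <- c(0.5, 1.5, 3.0, 4.5, 6.3)
  weak_rel <- 0.7   # weakly hydrogen-bonded water absorbs less per mole
  list(
    single_gly    = single("gly", small_m),
    single_nmg    = single("nmg", small_m),
    single_tmg    = single("tmg", small_m),
    single_urea   = single("urea", small_m),
    single_trpzip = single("trpzip", c(0, 0.008, 0.016, 0.024, 0.035)),
    single_hewl   = single("hewl", c(0, 0.002, 0.004, 0.006, 0.008)),
    trpzip_tmg = pair("trpzip", 0.035, "tmg", tmg_m,
                      shared_amount(150, 0.035, 12, 0.6, 5), strong_band),
    hewl_tmg   = pair("hewl", 0.008, "tmg", tmg_m,
                      shared_amount(900, 0.008, 12, 0.6, 5), strong_band),
    trpzip_urea = pair("trpzip", 0.035, "urea", urea_m,
                       shared_amount(150, 0.035, 6, 0.85, 12), weak_band,
                       int_rel = weak_rel),
    hewl_urea   = pair("hewl", 0.008, "urea", urea_m,
                       shared_amount(900, 0.008, 6, 0.85, 12), weak_band,
                       int_rel = weak_rel),
    gly_urea = pair("gly", 1, "urea", urea_m,
                    shared_amount(7, 1, 6, 0.8, 8), weak_band,
                    int_rel = weak_rel),
    nmg_urea = pair("nmg", 1, "urea", c(0.5, 1.5, 3.0, 4.5, 5.91),
                    shared_amount(9, 1, 6, 0.7, 8), weak_band,
                    int_rel = weak_rel),
    gly_tmg = pair("gly", 1, "tmg", c(0.5, 1.0, 1.5, 2.0, 2.6, 2.93),
                   crossover_amount(5, 2.4),
                   list(center = 2545, fwhm = 130, eta = 0)),
    nmg_tmg = pair("nmg", 1, "tmg", c(0.25, 0.5, 0.75, 1.5, 2.2, 2.93),
                   crossover_amount(8, 1.0),
                   list(center = 2470, fwhm = 120, eta = 0)),
    additive_gly_tmg = pair("gly", 1, "tmg", c(0.5, 1, 1.5, 2, 2.5),
                            NULL, NULL))
}
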