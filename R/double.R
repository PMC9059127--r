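#' Affected count for the 1 + beta solute set
#'
#' Rescales an affected number per combined mole of solutes to the count for
#' a set of 1 mol biomolecule plus `beta` mol osmolyte:
#' `N_p = N * (beta + 1)`.
#'
#' @param N affected number per combined mole of solutes.
#' @param beta molar ratio osmolyte : biomolecule (>= 0).
#' @return `N * (beta + 1)`.
#' @examples
#' np_transform(2, 4)  # 10
#' @export
np_transform <- function(N, beta) {
  if (any(beta < 0)) stop("beta must be non-negative", call. = FALSE)
  N * (beta + 1)
}

#' "Experimental" affected water of a two-solute sample
#'
#' Treats the biomolecule + osmolyte pair as one pseudo-solute of combined
#' molality `m_m + m_o` and isolates its affected water by the difference
#' method, using the secant `(eps(m_tot) - eps_b) / m_tot` through the bulk
#' spectrum as the concentration derivative (exact for mixtures linear in
#' molality, and identical to the single-solute result when `m_o = 0`).
#'
#' @param sample a [solution_sample()] containing both solutes.
#' @param bulk bulk-water `hdo_spectrum` (molar absorptivity), e.g. the
#'   intercept of a single-solute fit.
#' @param window analysis window, cm^-1.
#' @param smooth_n Savitzky-Golay pre-smoothing window (points, quadratic)
#'   for the sample spectrum; 1 disables.
#' @param N_scan,n_scan_points passed to [estimate_N()].
#' @param density_kg_dm3,molar_mass_water unit-conversion constants.
#' @return List with `spectrum` (affected water per combined mole), `N_e`,
#'   `derivative`, `trace` and `noise_sd` (per-point sd of the derivative).
#' @export
experimental_affected <- function(sample, bulk, window = c(2200, 2750),
                                  smooth_n = 25L,
                                  N_scan = c(0.5, 5000),
                                  n_scan_points = 120L,
                                  density_kg_dm3 = 1.0,
                                  molar_mass_water = 0.018015) {
  m_tot <- total_molality(sample)
  if (m_tot <= 0) stop("sample contains no solute", call. = FALSE)
  eps <- sample_epsilon(sample, window, density_kg_dm3)
  if (length(eps$wavenumber) != length(bulk$wavenumber) ||
      max(abs(eps$wavenumber - bulk$wavenumber)) > 1e-9)
    eps <- resample(eps, bulk$wavenumber)
  noise_sd <- noise_floor(eps$intensity) * sg_noise_factor(smooth_n) / m_tot
  deriv <- bulk
  deriv$intensity <- (sg_smooth(eps$intensity, smooth_n) - bulk$intensity) /
    m_tot
  deriv$meta$label <- "secant derivative (pseudo-solute)"
  est <- estimate_N(bulk, deriv, noise_sd = noise_sd, N_scan = N_scan,
                    n_scan_points = n_scan_points,
                    molar_mass_water = molar_mass_water)
  spec <- affected_spectrum(bulk, deriv, est$N,
                            molar_mass_water = molar_mass_water)
  spec$meta$label <- "experimental affected water"
  list(spectrum = spec, N_e = est$N, derivative = deriv, trace = est$trace,
       noise_sd = noise_sd)
}

#' "Synthetic" (no-interaction) affected water
#'
#' The composition-weighted mixture of the two single-solute affected-water
#' spectra: the hypothetical case of hydration spheres isolated in solution.
#' `N_s = n_m N_m + n_o N_o`; the spectrum is the intensity-weighted mixture
#' per combined mole of solutes.
#'
#' @param fit_m,fit_o [fit_affected_water()] results for the biomolecule and
#'   the osmolyte.
#' @param n_m,n_o mole fractions of the two solutes, summing to 1.
#' @return List with `spectrum` and `N_s`.
#' @export
synthetic_affected <- function(fit_m, fit_o, n_m, n_o) {
  if (abs(n_m + n_o - 1) > 1e-12)
    stop("mole fractions must sum to 1", call. = FALSE)
  if (n_o == 0) {
    spec <- fit_m$affected_spectrum
    spec$meta$label <- "synthetic affected water"
    return(list(spectrum = spec, N_s = fit_m$N))
  }
  if (n_m == 0) {
    spec <- fit_o$affected_spectrum
    spec$meta$label <- "synthetic affected water"
    return(list(spectrum = spec, N_s = fit_o$N))
  }
  N_s <- n_m * fit_m$N + n_o * fit_o$N
  spec <- spec_lincomb(c(n_m * fit_m$N, n_o * fit_o$N) / N_s,
                       list(fit_m$affected_spectrum, fit_o$affected_spectrum),
                       label = "synthetic affected water")
  list(spectrum = spec, N_s = N_s)
}

#' Isolate the double-affected water spectrum
#'
#' Subtracts the synthetic from the experimental affected intensity (per
#' combined mole of solutes): `D(nu) = N_e eps_e(nu) - N_s eps_s(nu)`,
#' `N_double = N_e - N_s`. A positive count signals cross-linking water drawn
#' from the bulk; a negative count signals water shared by overlapping
#' hydration spheres, in which case both the contour and the count are negated
#' so the returned spectrum is the positive contour of the shared water. The
#' returned spectrum is renormalized to molar absorptivity per mole of
#' double-affected water; `raw_difference` retains `D` so the experimental
#' intensity can be reconstructed exactly.
#'
#' @param experimental list from [experimental_affected()] (or `spectrum` +
#'   `N_e`).
#' @param synthetic list from [synthetic_affected()].
#' @param uncertainty_floor smallest |N_e - N_s| regarded as significant;
#'   below it the regime is `"additive"` and the (unnormalizable) spectrum is
#'   flagged low-confidence.
#' @return List with `spectrum`, `N_double` (signed: `N_e - N_s`), `regime`,
#'   `raw_difference`, `low_confidence`.
#' @export
double_affected <- function(experimental, synthetic, uncertainty_floor = 0) {
  common_grid(experimental$spectrum, synthetic$spectrum)
  N_e <- experimental$N_e
  N_s <- synthetic$N_s
  D <- experimental$spectrum
  D$intensity <- N_e * experimental$spectrum$intensity -
    N_s * synthetic$spectrum$intensity
  D$meta$label <- "experimental - synthetic intensity"
  N_double <- N_e - N_s
  if (abs(N_double) <= uncertainty_floor) {
    spec <- D
    spec$meta$label <- "double-affected water (low confidence)"
    return(list(spectrum = spec, N_double = N_double, regime = "additive",
                raw_difference = D, low_confidence = TRUE))
  }
  regime <- if (N_double > 0) "cross_linking" else "shared_overlap"
  spec <- D
  spec$intensity <- D$intensity / N_double   # negates in the shared regime
  spec$meta$label <- sprintf("double-affected water (%s)", regime)
  list(spectrum = spec, N_double = N_double, regime = regime,
       raw_difference = D, low_confidence = FALSE)
}

# Monte-Carlo sd of N_e under resampled spectral noise. The per-point white
# noise of the raw (unsmoothed) molar-absorptivity spectrum is estimated from
# its second differences; each draw adds fresh noise, applies the same
# Savitzky-Golay smoothing as the analysis path, and re-runs the N estimator.
mc_Ne_sd <- function(eps_raw, bulk, m_tot, window, draws = 200L,
                     seed = 20220420, smooth_n = 25L,
                     N_scan = c(0.5, 5000),
                     molar_mass_water = 0.018015) {
  sd_pt <- noise_floor(eps_raw$intensity)
  if (sd_pt <= 0) return(0)
  n <- length(eps_raw$intensity)
  base <- sg_smooth(eps_raw$intensity, smooth_n)
  noise_sd <- sd_pt * sg_noise_factor(smooth_n) * sqrt(2) / m_tot
  with_seed(seed, function() {
    draws_N <- vapply(seq_len(draws), function(i) {
      pert <- base + sg_smooth(stats::rnorm(n, 0, sd_pt), smooth_n)
      deriv <- bulk
      deriv$intensity <- (pert - bulk$intensity) / m_tot
      tryCatch(
        estimate_N(bulk, deriv, noise_sd = noise_sd, N_scan = N_scan,
                   molar_mass_water = molar_mass_water)$N,
        error = function(e) NA_real_)
    }, 0)
    # robust scale: the estimator's draw distribution is right-skewed
    stats::mad(draws_N, na.rm = TRUE)
  })
}

#' Fit the double-affected water model at one composition point
#'
#' Full two-solute analysis of a single sample containing a biomolecule (or
#' unfolded-protein model) and an osmolyte: computes the experimental and
#' synthetic affected spectra, isolates the double-affected water, classifies
#' the interaction regime, and reports the `N_p` transforms for the set of
#' 1 mol biomolecule + beta mol osmolyte.
#'
#' @param sample a [solution_sample()] with both solutes present.
#' @param fit_m,fit_o single-solute [fit_affected_water()] results for the
#'   biomolecule and the osmolyte (the biomolecule fit supplies the bulk
#'   spectrum).
#' @param window analysis window, cm^-1.
#' @param smooth_n Savitzky-Golay pre-smoothing window, see
#'   [experimental_affected()].
#' @param N_scan passed to the N estimator.
#' @param mc_draws Monte-Carlo draws for the regime uncertainty floor
#'   (0 disables; then a 1e-6 relative floor is used).
#' @param mc_seed seed for the uncertainty resampling.
#' @param density_kg_dm3,molar_mass_water unit-conversion constants.
#' @return An object of class `double_affected` with the experimental,
#'   synthetic and double spectra, `N_e`, `N_s`, `N_double`, `N_pe`, `N_ps`,
#'   `beta`, `n_m`, `n_o`, `regime` and diagnostics.
#' @examples
#' \donttest{
#' gen <- generate_series(preset_scenario("gly_urea"))
#' fm <- fit_affected_water(generate_series(preset_scenario("single_gly"))$series)
#' fo <- fit_affected_water(generate_series(preset_scenario("single_urea"))$series)
#' fit_double_affected(gen$series$samples[[3]], fm, fo)
#' }
#' @export
fit_double_affected <- function(sample, fit_m, fit_o,
                                window = c(2200, 2750),
                                smooth_n = 25L,
                                N_scan = c(0.5, 5000),
                                mc_draws = 200L, mc_seed = 20220420,
                                density_kg_dm3 = 1.0,
                                molar_mass_water = 0.018015) {
  m_m <- sample_molality(sample, fit_m$solute$name)
  m_o <- sample_molality(sample, fit_o$solute$name)
  if (m_m <= 0)
    stop("sample does not contain the biomolecule solute '",
         fit_m$solute$name, "'", call. = FALSE)
  beta <- m_o / m_m
  n_m <- 1 / (1 + beta)
  n_o <- beta / (1 + beta)
  bulk <- fit_m$bulk_spectrum
  exp_res <- experimental_affected(sample, bulk, window = window,
                                   smooth_n = smooth_n, N_scan = N_scan,
                                   density_kg_dm3 = density_kg_dm3,
                                   molar_mass_water = molar_mass_water)
  syn_res <- synthetic_affected(fit_m, fit_o, n_m, n_o)
  common_grid(exp_res$spectrum, syn_res$spectrum)
  floor_N <- 1e-6 * syn_res$N_s
  sd_Ne <- 0
  if (mc_draws > 0) {
    eps <- sample_epsilon(sample, window, density_kg_dm3)
    if (max(abs(eps$wavenumber - bulk$wavenumber)) > 1e-9)
      eps <- resample(eps, bulk$wavenumber)
    sd_Ne <- mc_Ne_sd(eps, bulk, m_m + m_o, window, draws = mc_draws,
                      seed = mc_seed, smooth_n = smooth_n, N_scan = N_scan,
                      molar_mass_water = molar_mass_water)
    floor_N <- max(floor_N, 2 * sd_Ne)
  }
  dbl <- double_affected(exp_res, syn_res, uncertainty_floor = floor_N)
  structure(
    list(experimental_spectrum = exp_res$spectrum, N_e = exp_res$N_e,
         synthetic_spectrum = syn_res$spectrum, N_s = syn_res$N_s,
         double_spectrum = dbl$spectrum, N_double = dbl$N_double,
         raw_difference = dbl$raw_difference,
         regime = dbl$regime, low_confidence = dbl$low_confidence,
         beta = beta, n_m = n_m, n_o = n_o,
         m_m = m_m, m_o = m_o,
         N_pe = np_transform(exp_res$N_e, beta),
         N_ps = np_transform(syn_res$N_s, beta),
         window = window,
         diagnostics = list(N_search_trace = exp_res$trace,
                            sd_Ne = sd_Ne, uncertainty_floor = floor_N,
                            # expected rms of N_e eps_e - N_s eps_s under no
                            # interaction: spectral noise through the
                            # derivative plus the N_e uncertainty acting on
                            # the bulk contour (dD/dN_e = eps_b)
                            noise_floor_double = sqrt(
                              (exp_res$noise_sd / molar_mass_water)^2 +
                                sd_Ne^2 * mean(bulk$intensity^2)),
                            mc_draws = mc_draws, mc_seed = mc_seed)),
    class = "double_affected")
}

#' @export
print.double_affected <- function(x, ...) {
  cat(sprintf("Double-affected water at m_o = %.3g mol/kg (beta = %.3g)\n",
              x$m_o, x$beta))
  cat(sprintf("  N_e = %.3f, N_s = %.3f, N_double = %+.3f  [%s%s]\n",
              x$N_e, x$N_s, x$N_double, x$regime,
              if (x$low_confidence) ", low confidence" else ""))
  cat(sprintf("  N_pe = %.2f, N_ps = %.2f per mol biomolecule\n",
              x$N_pe, x$N_ps))
  invisible(x)
}

#' @export
coef.double_affected <- function(object, ...) {
  c(N_e = object$N_e, N_s = object$N_s, N_double = object$N_double,
    N_pe = object$N_pe, N_ps = object$N_ps, beta = object$beta)
}

#' @export
summary.double_affected <- function(object, ...) {
  nu_g <- if (!object$low_confidence)
    gravity_center(object$double_spectrum, object$window) else NA_real_
  out <- c(as.list(coef(object)),
           list(regime = object$regime, nu_g_double = nu_g,
                low_confidence = object$low_confidence))
  class(out) <- "summary.double_affected"
  out
}

#' @export
print.summary.double_affected <- function(x, ...) {
  cat(sprintf("regime: %s   N_e %.3f  N_s %.3f  N_double %+.3f\n",
              x$regime, x$N_e, x$N_s, x$N_double))
  if (is.finite(x$nu_g_double))
    cat(sprintf("double-affected gravity center: %.1f cm^-1\n", x$nu_g_double))
  invisible(x)
}

#' @export
plot.double_affected <- function(x, ...) {
  nu <- x$experimental_spectrum$wavenumber
  ylim <- range(0, x$experimental_spectrum$intensity,
                x$synthetic_spectrum$intensity, x$double_spectrum$intensity)
  graphics::plot(nu, x$experimental_spectrum$intensity, type = "l",
                 xlab = expression(tilde(nu) ~ (cm^-1)),
                 ylab = "molar absorptivity", ylim = ylim, ...)
  graphics::lines(nu, x$synthetic_spectrum$intensity, lty = 2)
  graphics::lines(nu, x$double_spectrum$intensity, col = 2)
  graphics::legend("topright",
                   c("experimental", "synthetic", "double-affected"),
                   lty = c(1, 2, 1), col = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Titration profile of a two-solute series
#'
#' Runs [fit_double_affected()] at every osmolyte molality of a two-solute
#' titration series and tabulates the affected counts and interaction regime,
#' the quantities plotted against osmolyte molality in hydration studies.
#'
#' @param series a [solution_series()] with the biomolecule constant and the
#'   osmolyte varied (samples with zero osmolyte molality are skipped: there
#'   the synthetic and experimental constructions coincide by definition).
#' @param fit_m,fit_o single-solute fits of the two components.
#' @param ... passed to [fit_double_affected()].
#' @return A data frame of class `hydration_profile` with columns `m_o`,
#'   `beta`, `N_e`, `N_s`, `N_pe`, `N_ps`, `regime`, `nu_g_double`; the
#'   per-molality fits are attached as attribute `"fits"`.
#' @export
titration_profile <- function(series, fit_m, fit_o, ...) {
  stopifnot(inherits(series, "solution_series"))
  keep <- vapply(series$samples, sample_molality, 0,
                 solute_name = fit_o$solute$name) > 0
  samples <- series$samples[keep]
  if (length(samples) < 1L)
    stop("series contains no sample with non-zero osmolyte molality",
         call. = FALSE)
  fits <- lapply(samples, fit_double_affected, fit_m = fit_m, fit_o = fit_o,
                 ...)
  rows <- lapply(fits, function(f) {
    s <- summary(f)
    data.frame(m_o = f$m_o, beta = f$beta, N_e = f$N_e, N_s = f$N_s,
               N_pe = f$N_pe, N_ps = f$N_ps, regime = f$regime,
               nu_g_double = s$nu_g_double)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("hydration_profile", "data.frame")
  out
}

#' @export
plot.hydration_profile <- function(x, ...) {
  ylim <- range(x$N_pe, x$N_ps)
  graphics::plot(x$m_o, x$N_pe, type = "b", col = 2, pch = 15,
                 xlab = expression(m[o] ~ (mol ~ kg^-1)),
                 ylab = expression(N[p]), ylim = ylim, ...)
  graphics::lines(x$m_o, x$N_ps, type = "b", pch = 15)
  graphics::legend("topleft", c("experimental", "synthetic"),
                   col = c(2, 1), pch = 15, bty = "n")
  invisible(x)
}
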