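`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal quadrature
#'
#' @param x abscissa, strictly increasing.
#' @param y ordinate, same length as `x`.
#' @return The integral of `y` over `x`.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Pseudo-Voigt band profile
#'
#' Linear mixture of a Gaussian and a Lorentzian of common full width at half
#' maximum, the standard empirical lineshape for condensed-phase vibrational
#' bands.
#'
#' @param nu wavenumber grid (cm^-1).
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @param height peak height.
#' @return Numeric vector of intensities, `height` at `center`.
#' @examples
#' nu <- seq(2200, 2750, by = 1)
#' band <- pseudo_voigt(nu, 2505, 160, 0.15)
#' @export
pseudo_voigt <- function(nu, center, fwhm, eta = 0, height = 1) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-(nu - center)^2 / (2 * sigma^2))
  l <- (fwhm / 2)^2 / ((nu - center)^2 + (fwhm / 2)^2)
  height * ((1 - eta) * g + eta * l)
}

# Robust per-point noise estimate from second differences of a sampled
# signal: double differencing annihilates locally linear band structure and
# leaves sqrt(6) x the white-noise sd; the median absolute deviation makes it
# outlier-safe. Smooth noiseless bands give a near-zero floor.
noise_floor <- function(y) {
  d <- diff(y, differences = 2L)
  stats::mad(d) / sqrt(6)
}

# Evaluate f() with the RNG advanced from `seed` and the caller's RNG state
# restored afterwards, so seeded generation never perturbs a session.
with_seed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

# centered running mean with reflected ends (odd k)
runmean <- function(y, k) {
  n <- length(y)
  if (k <= 1L || n < k) return(y)
  h <- (k - 1L) %/% 2L
  yp <- c(rev(y[seq_len(h) + 1L]), y, rev(y[n - seq_len(h)]))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2L))[(h + 1L):(h + n)]
}

# Savitzky-Golay smoothing (quadratic, odd window) and the factor by which
# the filter reduces the marginal sd of white noise (root sum of squared
# central kernel weights)
sg_smooth <- function(y, n = 25L, p = 2L) {
  if (n <= 1L || length(y) <= n) return(y)
  signal::sgolayfilt(y, p = p, n = n)
}

sg_noise_factor <- function(n = 25L, p = 2L) {
  if (n <= 1L) return(1)
  k <- signal::sgolay(p = p, n = n)
  sqrt(sum(k[(n + 1L) %/% 2L, ]^2))
}

# moles of water per kg of water
water_moles_per_kg <- function(molar_mass_water = 0.018015) 1 / molar_mass_water
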