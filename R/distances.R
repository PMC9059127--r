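#' Empirical OD-wavenumber / O...O-distance calibration
#'
#' Encodes the empirical correlation between the OD stretching wavenumber of
#' an HDO molecule and the O...O distance of the hydrogen bond it donates, as
#' an exponential Badger-Bauer-type law
#' `nu(R) = nu_inf - A * exp(-R / b)`,
#' anchored at two reference points: ice Ih (2420 cm^-1 at 2.76 A) and the
#' ambient-water OD band maximum (2505 cm^-1 at 2.83 A). `A` and `b` are
#' derived from the anchors; all coefficients are configurable so an
#' alternative literature correlation can be swapped in.
#'
#' @param nu_inf asymptotic wavenumber of the correlation (cm^-1).
#' @param anchors 2x2 matrix-like: rows `(nu, R)` of the two anchor points.
#' @param valid_range wavenumber range over which the correlation is applied.
#' @return An object of class `od_distance_calibration` with fields
#'   `nu_inf`, `A`, `b`, `valid_range`.
#' @examples
#' cal <- od_distance_calibration()
#' wavenumber_to_distance(2505, cal)   # 2.83 A by construction
#' @export
od_distance_calibration <- function(nu_inf = 3000,
                                    anchors = rbind(c(2505, 2.83),
                                                    c(2420, 2.76)),
                                    valid_range = c(2200, 2750)) {
  anchors <- as.matrix(anchors)
  stopifnot(nrow(anchors) == 2, all(nu_inf > anchors[, 1]),
            max(valid_range) < nu_inf)
  b <- (anchors[1, 2] - anchors[2, 2]) /
    log((nu_inf - anchors[2, 1]) / (nu_inf - anchors[1, 1]))
  A <- (nu_inf - anchors[1, 1]) * exp(anchors[1, 2] / b)
  stopifnot(b > 0, A > 0)
  structure(list(nu_inf = nu_inf, A = A, b = b,
                 valid_range = sort(valid_range)),
            class = "od_distance_calibration")
}

#' @export
print.od_distance_calibration <- function(x, ...) {
  cat(sprintf(
    "<od_distance_calibration> nu(R) = %.6g - %.6g * exp(-R / %.6g), valid %g-%g cm^-1\n",
    x$nu_inf, x$A, x$b, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Map OD wavenumbers to O...O hydrogen-bond distances
#'
#' Strictly increasing over the calibrated range: red-shifted OD oscillators
#' donate shorter (stronger) hydrogen bonds.
#'
#' @param nu wavenumbers, cm^-1, inside the calibration's valid range.
#' @param calibration an [od_distance_calibration()].
#' @return O...O distances in Angstrom.
#' @export
wavenumber_to_distance <- function(nu, calibration = od_distance_calibration()) {
  vr <- calibration$valid_range
  if (any(nu < vr[1] - 1e-9 | nu > vr[2] + 1e-9))
    stop(sprintf("wavenumber outside the calibrated range [%g, %g] cm^-1",
                 vr[1], vr[2]), call. = FALSE)
  calibration$b * log(calibration$A / (calibration$nu_inf - nu))
}

#' @rdname wavenumber_to_distance
#' @param R O...O distances in Angstrom.
#' @export
distance_to_wavenumber <- function(R, calibration = od_distance_calibration()) {
  nu <- calibration$nu_inf - calibration$A * exp(-R / calibration$b)
  vr <- calibration$valid_range
  if (any(nu < vr[1] - 1e-6 | nu > vr[2] + 1e-6))
    stop("distance maps outside the calibrated wavenumber range", call. = FALSE)
  nu
}

#' Transform a spectral contour into an O...O distance distribution
#'
#' Change of variables through the empirical calibration:
#' `P(R) = A(nu(R)) * |dnu/dR|`, evaluated on a uniform distance grid and
#' normalized to unit area. The mode of `P(R)` is the most probable
#' hydrogen-bond O...O distance of the probed water population.
#'
#' @param s an `hdo_spectrum`, non-negative within the window.
#' @param window analysis window, cm^-1 (intersected with the calibration's
#'   valid range).
#' @param calibration an [od_distance_calibration()].
#' @param dr distance grid step, Angstrom.
#' @return An object of class `distance_distribution` with fields
#'   `distance` (A), `density` (per A, unit area) and `mode` (A).
#' @export
distance_distribution <- function(s, window = c(2200, 2750),
                                  calibration = od_distance_calibration(),
                                  dr = 0.002) {
  window <- c(max(min(window), calibration$valid_range[1]),
              min(max(window), calibration$valid_range[2]))
  cs <- clip_window(s, window)
  if (trapz(cs$wavenumber, cs$intensity) <= 0)
    stop("degenerate (zero-area) band; distance distribution undefined",
         call. = FALSE)
  r_lim <- wavenumber_to_distance(range(cs$wavenumber), calibration)
  R <- seq(r_lim[1], r_lim[2], by = dr)
  nuR <- distance_to_wavenumber(R, calibration)
  A_nu <- stats::approx(cs$wavenumber, pmax(cs$intensity, 0), xout = nuR,
                        rule = 2)$y
  jac <- (calibration$A / calibration$b) * exp(-R / calibration$b)  # dnu/dR > 0
  dens <- A_nu * jac
  dens <- dens / trapz(R, dens)
  structure(list(distance = R, density = dens, mode = R[which.max(dens)],
                 window = window),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %d points, %.3f-%.3f A, mode %.3f A\n",
              length(x$distance), min(x$distance), max(x$distance), x$mode))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...,
                                       xlab = expression(R[OO] ~ (ring(A))),
                                       ylab = expression(P(R[OO]))) {
  graphics::plot(x$distance, x$density, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(v = x$mode, lty = 3)
  invisible(x)
}

#' Difference between two distance distributions
#'
#' `delta_P = P(a) - P(b)` on the common part of the two distance grids.
#' A positive lobe at short R signals a gain of strong hydrogen bonds in `a`
#' relative to `b`; since both densities integrate to one over their own
#' support, the difference integrates to zero when the supports coincide.
#'
#' @param a,b `distance_distribution` objects with overlapping supports.
#' @return A data frame with columns `distance` and `delta_density`.
#' @export
delta_P <- function(a, b) {
  lo <- max(min(a$distance), min(b$distance))
  hi <- min(max(a$distance), max(b$distance))
  if (lo >= hi)
    stop("distance distributions have disjoint supports", call. = FALSE)
  R <- seq(lo, hi, by = min(diff(a$distance)[1], diff(b$distance)[1]))
  da <- stats::approx(a$distance, a$density, xout = R)$y
  db <- stats::approx(b$distance, b$density, xout = R)$y
  data.frame(distance = R, delta_density = da - db)
}

#' Mean O...O distance of a distribution
#'
#' @param x a `distance_distribution`.
#' @return First moment, Angstrom.
#' @export
mean_distance <- function(x) {
  trapz(x$distance, x$distance * x$density) / trapz(x$distance, x$density)
}
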