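#' Construct an infrared spectrum
#'
#' The universal currency of the package: a sampled absorption contour on a
#' strictly increasing wavenumber grid, carrying the acquisition metadata
#' needed for unit conversions. Intensities are either raw absorbance or molar
#' absorptivity per mole of water (dm^3 mol^-1 cm^-1); the latter is the scale
#' on which all affected-water algebra is done.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1). A descending grid
#'   is reversed on construction; all stored spectra are ascending.
#' @param intensity numeric vector of intensities, same length.
#' @param kind `"absorbance"` or `"molar_absorptivity"`.
#' @param path_length_mm cell path length (mm); required for unit conversion
#'   of absorbance spectra.
#' @param temperature_C temperature (Celsius).
#' @param label free-text label.
#' @return An object of class `hdo_spectrum`.
#' @examples
#' s <- hdo_spectrum(seq(2200, 2750, 2),
#'                   pseudo_voigt(seq(2200, 2750, 2), 2505, 160, 0.15),
#'                   path_length_mm = 0.029)
#' @export
hdo_spectrum <- function(wavenumber, intensity,
                         kind = c("absorbance", "molar_absorptivity"),
                         path_length_mm = NA_real_,
                         temperature_C = 25,
                         label = "") {
  kind <- match.arg(kind)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  if (length(wavenumber) < 8L)
    stop("a spectrum needs at least 8 points", call. = FALSE)
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity)))
    stop("non-finite values in spectrum", call. = FALSE)
  if (all(diff(wavenumber) < 0)) {          # instrument-native descending grid
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  }
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid is not strictly monotone (duplicate or unsorted points)",
         call. = FALSE)
  structure(
    list(wavenumber = wavenumber, intensity = intensity, kind = kind,
         meta = list(path_length_mm = path_length_mm,
                     temperature_C = temperature_C, label = label)),
    class = "hdo_spectrum")
}

is_hdo_spectrum <- function(x) inherits(x, "hdo_spectrum")

assert_spectrum <- function(x, arg = deparse(substitute(x))) {
  if (!is_hdo_spectrum(x)) stop(arg, " is not an hdo_spectrum", call. = FALSE)
  invisible(x)
}

#' @export
print.hdo_spectrum <- function(x, ...) {
  cat(sprintf("<hdo_spectrum> %s\n", x$meta$label))
  cat(sprintf("  %d points, %.1f-%.1f cm^-1, %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$kind))
  cat(sprintf("  max intensity %.4g at %.1f cm^-1\n",
              max(x$intensity), x$wavenumber[which.max(x$intensity)]))
  invisible(x)
}

#' @export
as.data.frame.hdo_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' @export
plot.hdo_spectrum <- function(x, ...,
                              xlab = expression(tilde(nu) ~ (cm^-1)),
                              ylab = x$kind, type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Supports plain two-column text (wavenumber, intensity; whitespace- or
#' comma-delimited, `#` comments) and the JCAMP-DX `(X++(Y..Y))` AFFN XYDATA
#' dialect. Descending instrument grids are normalized to ascending order.
#'
#' @param path file path.
#' @param format `"two_column_text"`, `"jcamp_dx"`, or `"auto"` (by
#'   extension/content).
#' @param ... passed to [hdo_spectrum()] (metadata overrides).
#' @return An `hdo_spectrum`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "two_column_text", "jcamp_dx"),
                          ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^##", first)) "jcamp_dx" else "two_column_text"
  }
  switch(format,
         two_column_text = read_two_column(path, ...),
         jcamp_dx = read_jcamp(path, ...))
}

read_two_column <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  fields <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: expected two columns",
                 path, rows[bad[1]]), call. = FALSE)
  x <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: non-numeric field",
                 path, rows[bad[1]]), call. = FALSE)
  hdo_spectrum(x, y, label = basename(path), ...)
}

# Minimal JCAMP-DX: fixed-point AFFN "(X++(Y..Y))" XYDATA blocks, the form
# emitted by write_spectrum(). XFACTOR/YFACTOR/FIRSTX/LASTX/NPOINTS honored.
read_jcamp <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    i <- grep(paste0("^##", name, "\\s*="), lines)
    if (!length(i)) return(NULL)
    trimws(sub("^##[^=]*=", "", lines[i[1]]))
  }
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  npt <- as.numeric(get_field("NPOINTS") %||% NA)
  i0 <- grep("^##XYDATA\\s*=", lines)
  if (!length(i0)) stop("parse error in ", path, ": no ##XYDATA block",
                        call. = FALSE)
  i1 <- grep("^##END", lines)
  i1 <- i1[i1 > i0[1]]
  if (!length(i1)) stop("parse error in ", path, ": unterminated XYDATA",
                        call. = FALSE)
  body <- lines[(i0[1] + 1L):(i1[1] - 1L)]
  x <- numeric(0); y <- numeric(0)
  for (k in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[k]), "[ \t,;]+")[[1]]))
    if (length(vals) < 2L || any(!is.finite(vals)))
      stop(sprintf("parse error in %s at line %d: bad AFFN data",
                   path, i0[1] + k), call. = FALSE)
    x <- c(x, vals[1])
    y <- c(y, vals[-1])
  }
  if (!is.na(npt) && length(y) != npt)
    stop(sprintf("data error in %s: NPOINTS=%d but %d ordinates read",
                 path, npt, length(y)), call. = FALSE)
  # reconstruct the full abscissa from the header range and uniform spacing
  firstx <- get_field("FIRSTX")
  firstx <- if (is.null(firstx)) x[1] * xf else as.numeric(firstx)
  lastx <- get_field("LASTX")
  n <- length(y)
  if (is.null(lastx)) stop("parse error in ", path, ": LASTX missing", call. = FALSE)
  lastx <- as.numeric(lastx)
  grid <- seq(firstx, lastx, length.out = n)
  hdo_spectrum(grid, y * yf,
               temperature_C = as.numeric(get_field("TEMPERATURE") %||% "25"),
               path_length_mm = as.numeric(get_field("PATHLENGTH") %||% NA),
               label = get_field("TITLE") %||% basename(path), ...)
}

#' Write a spectrum to disk
#'
#' @param s an `hdo_spectrum`.
#' @param path destination file.
#' @param format `"two_column_text"` or `"jcamp_dx"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path,
                           format = c("two_column_text", "jcamp_dx")) {
  assert_spectrum(s)
  format <- match.arg(format)
  if (format == "two_column_text") {
    writeLines(sprintf("%.10g %.12g", s$wavenumber, s$intensity), path)
  } else {
    n <- length(s$wavenumber)
    hdr <- c(
      sprintf("##TITLE=%s", s$meta$label),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      sprintf("##TEMPERATURE=%.6g", s$meta$temperature_C),
      if (is.finite(s$meta$path_length_mm))
        sprintf("##PATHLENGTH=%.6g", s$meta$path_length_mm),
      "##XFACTOR=1", "##YFACTOR=1",
      sprintf("##FIRSTX=%.10g", s$wavenumber[1]),
      sprintf("##LASTX=%.10g", s$wavenumber[n]),
      sprintf("##NPOINTS=%d", n),
      "##XYDATA=(X++(Y..Y))")
    body <- vapply(seq_len(n), function(i)
      sprintf("%.10g %.12g", s$wavenumber[i], s$intensity[i]), "")
    writeLines(c(hdr, body, "##END="), path)
  }
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Interpolation is shape-preserving piecewise cubic (Fritsch-Carlson
#' monotone Hermite) by default, which avoids ringing on band shoulders;
#' linear interpolation is available. Extrapolation is refused.
#'
#' @param s an `hdo_spectrum`.
#' @param grid target wavenumber grid (cm^-1), inside the support of `s`.
#' @param method `"monotone_cubic"` or `"linear"`.
#' @return An `hdo_spectrum` on `grid`.
#' @export
resample <- function(s, grid, method = c("monotone_cubic", "linear")) {
  assert_spectrum(s)
  method <- match.arg(method)
  grid <- sort(as.numeric(grid))
  if (min(grid) < min(s$wavenumber) - 1e-9 ||
      max(grid) > max(s$wavenumber) + 1e-9)
    stop(sprintf("resample grid [%.2f, %.2f] extends beyond spectrum support [%.2f, %.2f]",
                 min(grid), max(grid), min(s$wavenumber), max(s$wavenumber)),
         call. = FALSE)
  y <- if (method == "linear") {
    stats::approx(s$wavenumber, s$intensity, xout = grid)$y
  } else {
    stats::splinefun(s$wavenumber, s$intensity, method = "monoH.FC")(grid)
  }
  out <- s
  out$wavenumber <- grid
  out$intensity <- y
  out
}

#' Clip a spectrum to a wavenumber window
#'
#' @param s an `hdo_spectrum`.
#' @param window length-2 numeric, `c(lo, hi)` in cm^-1.
#' @return The spectrum restricted to points inside the window.
#' @export
clip_window <- function(s, window) {
  assert_spectrum(s)
  keep <- s$wavenumber >= min(window) & s$wavenumber <= max(window)
  if (sum(keep) < 8L)
    stop("fewer than 8 points inside the analysis window", call. = FALSE)
  out <- s
  out$wavenumber <- s$wavenumber[keep]
  out$intensity <- s$intensity[keep]
  out
}

#' Convert absorbance to molar absorptivity per mole of water
#'
#' Applies the Beer-Lambert relation eps = A / (d * c_w) with the path length
#' in dm and the molar concentration of (total) water in the solution. The
#' inverse conversion is [to_absorbance()].
#'
#' @param s an `hdo_spectrum` with `kind = "absorbance"`.
#' @param water_molarity moles of water per dm^3 of solution.
#' @return An `hdo_spectrum` with `kind = "molar_absorptivity"`.
#' @export
to_molar_absorptivity <- function(s, water_molarity) {
  assert_spectrum(s)
  if (s$kind != "absorbance")
    stop("spectrum is not in absorbance units", call. = FALSE)
  d_mm <- s$meta$path_length_mm
  if (!is.finite(d_mm) || d_mm <= 0)
    stop("path_length_mm metadata missing; cannot convert to molar absorptivity",
         call. = FALSE)
  stopifnot(water_molarity > 0)
  out <- s
  out$intensity <- s$intensity / ((d_mm / 100) * water_molarity)
  out$kind <- "molar_absorptivity"
  out
}

#' @rdname to_molar_absorptivity
#' @export
to_absorbance <- function(s, water_molarity) {
  assert_spectrum(s)
  if (s$kind != "molar_absorptivity")
    stop("spectrum is not in molar absorptivity units", call. = FALSE)
  d_mm <- s$meta$path_length_mm
  if (!is.finite(d_mm) || d_mm <= 0)
    stop("path_length_mm metadata missing", call. = FALSE)
  out <- s
  out$intensity <- s$intensity * ((d_mm / 100) * water_molarity)
  out$kind <- "absorbance"
  out
}

#' Subtract a baseline anchored in signal-free windows
#'
#' Fits a straight line (or low-order polynomial) through the mean points of
#' user-named anchor windows and subtracts it.
#'
#' @param s an `hdo_spectrum`.
#' @param anchor_windows list of length-2 numeric intervals (cm^-1), each
#'   containing at least 2 sample points.
#' @param degree polynomial degree (1 = linear, default).
#' @return Baseline-subtracted `hdo_spectrum`.
#' @export
subtract_baseline <- function(s, anchor_windows, degree = 1L) {
  assert_spectrum(s)
  if (!length(anchor_windows)) stop("no anchor windows given", call. = FALSE)
  ax <- ay <- numeric(0)
  for (w in anchor_windows) {
    keep <- s$wavenumber >= min(w) & s$wavenumber <= max(w)
    if (sum(keep) < 2L)
      stop(sprintf("anchor window [%.1f, %.1f] contains fewer than 2 points",
                   min(w), max(w)), call. = FALSE)
    ax <- c(ax, mean(s$wavenumber[keep]))
    ay <- c(ay, mean(s$intensity[keep]))
  }
  degree <- min(degree, length(ax) - 1L)
  fit <- stats::lm(ay ~ stats::poly(ax, degree, raw = TRUE))
  base <- stats::predict(fit, newdata = data.frame(ax = s$wavenumber))
  out <- s
  out$intensity <- s$intensity - as.numeric(base)
  out
}

# elementwise arithmetic on aligned spectra ------------------------------

common_grid <- function(a, b, tol = 1e-6) {
  if (length(a$wavenumber) != length(b$wavenumber) ||
      max(abs(a$wavenumber - b$wavenumber)) > tol)
    stop("spectra are not on a common wavenumber grid; resample first",
         call. = FALSE)
  a$wavenumber
}

spec_lincomb <- function(coefs, spectra, kind = NULL, label = "") {
  g <- spectra[[1]]$wavenumber
  for (s in spectra[-1]) common_grid(spectra[[1]], s)
  y <- rep(0, length(g))
  for (i in seq_along(spectra)) y <- y + coefs[i] * spectra[[i]]$intensity
  out <- spectra[[1]]
  out$intensity <- y
  if (!is.null(kind)) out$kind <- kind
  out$meta$label <- label
  out
}
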