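---
title: "Quantitative difference spectra of solute-affected water: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative difference spectra of solute-affected water: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdoshell)
```

## The measurement and the model

Dilute HDO in H2O is a local probe of water structure: its OD stretching
band (roughly 2200-2750 cm^-1) is decoupled from the OH bath, and its
position reports the strength of the hydrogen bond the OD group donates.
`hdoshell` analyzes titration series of such spectra: for each composition a
sample (HDO-containing) spectrum and a matched H2O reference spectrum are
measured; their difference removes solute and H2O bands and isolates the OD
contour.

On the molar-absorptivity-per-mole-of-water scale, the quantitative
difference-spectra method writes the spectrum of a solution of molality $m$
as a mixture of bulk-like and solute-affected water. The affected-water
spectrum follows from the bulk spectrum $\varepsilon_b$ and the
concentration derivative at infinite dilution:

$$\varepsilon_a(\nu) \;=\; \varepsilon_b(\nu) \;+\;
  \frac{1}{N\,M}\,\left.\frac{\partial \varepsilon(\nu)}{\partial m}\right|_{m\to 0},$$

where $M$ = 0.018015 kg/mol is the molar mass of water and $N$ — the
affected number — is the moles of water perturbed by one mole of solute.
$N$ is not observed directly; it is the one free parameter of the
decomposition.

### Choosing N

The classical criterion is non-negativity: if $N$ is chosen too small, more
water is ascribed to the solute than the derivative supports and
$\varepsilon_a$ develops a negative lobe. `estimate_N()` takes the smallest
$N$ for which the negative-lobe area of $\varepsilon_a(N)$ is consistent
with the spectral noise. Concretely, for each candidate $N$ it compares the
observed negative-lobe area with the mean and standard deviation that pure
per-point Gaussian noise of the estimated level would produce around a
non-negative spectrum, and accepts once the observed area falls within half
a standard deviation of that expectation; the boundary is then refined by
root finding. For noiseless data the expectation is zero and the criterion
reduces to strict non-negativity, which recovers constructed affected
numbers to well under 1%.

A fixed negativity allowance (a percent-scale fraction of the band maximum)
is the form in which this criterion is usually quoted. We deliberately do
*not* use such a fixed allowance as the selection rule: because the bulk and
affected bands overlap strongly, an allowance of 0.5% of the band maximum
biases $N$ downward by 20-30% wherever the bulk intensity is a few percent
of the peak — the allowance is worth many percent of $N$ exactly where the
criterion binds. Instead the conventional -0.5%-of-maximum bound is kept as
a validity check on the returned spectrum (`tol` in
`fit_affected_water()`), and the selection itself is noise-anchored.

### Noise handling

Spectra are lightly smoothed before the derivative fit with a quadratic
Savitzky-Golay filter (default window `smooth_n = 25` points at 1 cm^-1
spacing, i.e. well below the ~160 cm^-1 band width). The per-point white
noise is estimated from second differences of the unsmoothed spectra
(`mad(diff(y, differences = 2))/sqrt(6)`), and the filter's known
noise-reduction factor propagates that estimate to the smoothed derivative,
so the N criterion sees a consistent noise level. Setting `smooth_n = 1`
disables smoothing.

The derivative itself is a per-wavenumber weighted least-squares fit of
$\varepsilon(m)$ over the whole series (linear by default, quadratic by
option); its intercept is the bulk-water spectrum, so a measured pure-water
sample is used when present but is not required.

## Two solutes: experimental, synthetic, and double-affected water

For a solution containing a biomolecule (molality $m_m$) and an osmolyte
($m_o$), the pair is treated as one pseudo-solute of molality $m_m + m_o$
with mole fractions $n_m = 1/(1+\beta)$, $n_o = \beta/(1+\beta)$,
$\beta = m_o/m_m$. The *experimental* affected spectrum and $N_e$ come from
the single-solute machinery applied to this pseudo-solute; since only one
sample exists per composition, the derivative is the secant through the
bulk spectrum, $(\varepsilon(m_{tot}) - \varepsilon_b)/m_{tot}$, which is
exact for mixtures linear in molality and reduces to the single-solute
result when $m_o = 0$.

The *synthetic* spectrum is the no-interaction construction from the pure
components: $N_s = n_m N_m + n_o N_o$ with the intensity-weighted mixture
spectrum. Their intensity-level difference

$$D(\nu) = N_e\,\varepsilon_e(\nu) - N_s\,\varepsilon_s(\nu), \qquad
  N_{double} = N_e - N_s$$

isolates the *double-affected* water. A positive count means extra water
drawn from the bulk that bridges the two hydration spheres (cross-linking);
a negative count means water shared by overlapping spheres, in which case
both $D$ and the count are negated so the returned contour is positive. The
returned spectrum is $D/N_{double}$, molar absorptivity per mole of
double-affected water; the signed bookkeeping round-trips exactly:
$N_s \varepsilon_s + N_{double}\,\varepsilon_{double} = N_e \varepsilon_e$
to machine precision on noiseless data. The exact renormalization used in
the original studies is not public; this first-order convention is adopted
because it preserves total affected intensity and is fully auditable
through the round-trip identity.

For comparison across compositions the counts are rescaled to the set
"1 mol biomolecule + $\beta$ mol osmolyte":
$N_{pe} = N_e(\beta+1)$, $N_{ps} = N_s(\beta+1)$.

### Regime calls and their uncertainty

Whether $N_{pe} < N_{ps}$ (shared) or $N_{pe} > N_{ps}$ (cross-linking) is
a statistical question near the crossover. The uncertainty of $N_e$ is
estimated by fixed-seed Monte-Carlo resampling (default 200 draws): fresh
noise at the estimated level is added to the measured spectrum, smoothed as
in the analysis path, and the N estimator re-run; the robust (MAD-based)
spread of the draws — the estimator's draw distribution is right-skewed —
sets the floor. Differences within twice this floor are reported as
`additive` and the double spectrum is flagged low-confidence. This
fixed-seed propagation stands in for the error-bar analysis of the original
measurements, which is not public.

## Band descriptors and O...O distances

The gravity center $\nu^g$ (trapezoidal first moment over the analysis
window) measures the mean hydrogen-bond energy through the Badger-Bauer
rule: lower wavenumber, stronger bond. $\Delta\nu^g = \nu^g_{double} -
\nu^g_m$ is negative when the osmolyte strengthens the hydrogen bonds of
the biomolecule's hydration water. The band maximum is located by quadratic
interpolation through the three highest samples, adequate below the 4
cm^-1 instrument resolution.

Spectral contours are transformed into donor-acceptor O...O distance
distributions by a change of variables through an empirical
wavenumber-distance correlation. The correlation is encoded as an
exponential Badger-Bauer-type law

$$\nu(R) = \nu_\infty - A\,e^{-R/b},$$

anchored at ice Ih (2420 cm^-1 at 2.76 Å) and at the ambient-water OD band
maximum (2505 cm^-1 at 2.83 Å), with $\nu_\infty$ = 3000 cm^-1; $A$ and
$b$ follow from the anchors. The literature correlation this stands in for
is cited but not restated in the source study, so the coefficients live in
`od_distance_calibration()` and an alternative (for example a different
asymptote, or a quasi-linear variant) can be swapped in without touching
the transform. $P(R) \propto A(\nu(R))\,|d\nu/dR|$ is evaluated on a
uniform grid (0.002 Å step, resolving the 0.01 Å tolerances used in this
field) and normalized to unit area. Differences
$\Delta P = P_{double} - P_m$ integrate to zero and localize the gained or
lost hydrogen-bond populations: mass below 2.83 Å is strengthened
(ice-like) water, mass above is weakened water.

The gravity center is computed over the full analysis window
(2200-2750 cm^-1 by default); the window is configurable and recorded in
all outputs, since the original truncation choice is not public.

## The synthetic-data generator

No raw spectra are deposited for the systems that motivated this package,
so `generate_series()` forward-models the whole measurement with known
ground truth, and every pipeline stage is validated against it. A scenario
is composed per kilogram of water: $W = 55.5$ mol of water splits into bulk
water, $N_i m_i$ moles affected by each solute, and signed interaction
water $X(m_o)$ (positive: cross-linking water with its own band, drawn from
the bulk; negative: water shared by the two spheres, removed from the
double-counted pool with the shared-water band as its signature). Molar
absorptivity is converted to absorbance via Beer-Lambert with the 0.029 mm
path length and a fixed solution density of 1.00 kg/dm^3 (the same
convention the analysis uses, so it cancels in recovery). Sample and
reference share a common background (baseline drift plus weak solute bands
at 2290 cm^-1) that the difference step must cancel. White Gaussian noise
with a fixed seed (20220420) is added to both members.

Generator choices worth stating:

* **Bulk band.** Pseudo-Voigt, 2505 cm^-1, FWHM 160 cm^-1, 15% Lorentzian
  — parameters chosen so that the encoded calibration maps the contour to a
  most-probable O...O distance of 2.83 Å, anchoring the generator to the
  accepted pure-water value. Affected-component bands are Gaussian with
  shifts and widths chosen per solute (stabilizer red-shifted, denaturant
  blue-shifted); shared-water bands for weakened water carry a reduced
  integrated intensity (0.7 of the bulk band area), consistent with the
  lower absorptivity of weak hydrogen bonds.
* **Study conditions.** Presets use the experimental design of the
  motivating study: model molecules at 1 mol/kg, the beta-hairpin peptide at
  0.035 and lysozyme at 0.008 mol/kg, osmolyte titrated up to 2.93 mol/kg
  (TMG) or 6.30/5.91 mol/kg (urea), D2O at 4% of water mass, 25 °C, 0.029
  mm path. The affected numbers themselves are not public (the supplement
  is unavailable); the presets use field-plausible values chosen once —
  urea 6, TMG 12, GLY 7, NMG 9, trpzip-1 150, lysozyme 900 — and the
  interaction amplitudes are set so that the shared/cross-linking
  separations are resolved relative to the propagated error bars at every
  plotted molality, as they are in the published figures. The model+TMG
  presets place the cross-linking-to-shared crossover at 2.4 (GLY) and 1.0
  mol/kg (NMG).
* **Noise.** Default 0.05% of the bulk absorbance band maximum,
  representative of a few-hundred-scan FTIR average; tests additionally
  exercise 0.1% and 0.2%.

What the generator does *not* emulate: atmospheric-line residuals,
instrument drift between sample and reference, baseline curvature beyond a
linear trend, lineshape physics beyond pseudo-Voigt mixtures, and any
nonlinearity of $\varepsilon(m)$ beyond the optional quadratic term.
Passing the generator-based tests therefore demonstrates the correctness
and calibration of the *analysis chain*, not the absence of such
instrumental systematics in real data.

## Numerical choices and degenerate inputs

* All spectra are stored on ascending wavenumber grids; descending
  instrument grids are reversed on read. Grids must agree to 1e-6 cm^-1
  before spectral algebra; `resample()` (shape-preserving monotone cubic by
  default, linear by option) is the only sanctioned way to move between
  grids, and it refuses extrapolation.
* The N scan is log-spaced over [0.5, 5000] (120 points) — the upper bound
  admits macromolecules with hydration numbers in the hundreds — and the
  accepted boundary is polished with `uniroot` to 1e-10.
* Derivative fits require at least 3 molalities (4 for the quadratic); a
  derivative whose amplitude is within 10x of its noise floor is refused
  rather than inverted.
* A zero-area band has no gravity center or distance distribution; both
  raise errors rather than returning NaN. `delta_P` requires overlapping
  distance supports.
* `|N_e - N_s|` below the uncertainty floor yields regime `additive` and an
  unnormalized (low-confidence) double spectrum, since dividing by a
  near-zero count would amplify noise without bound.

## Problem sizes

The test-suite and worked examples run on 651-point spectra (2150-2800
cm^-1 at 1 cm^-1), series of 5-6 molalities, 20-seed noise replicates, and
50-200 Monte-Carlo draws for uncertainty floors — sizes at which the full
chain (generation, single fits, titration profile, descriptors, distances)
completes in seconds to a few minutes on one core.

## Known limitations

* The secant derivative for two-solute samples is exact only for mixtures
  linear in total molality; strongly saturating hydration would need
  composition-ray titrations that the original design does not provide.
* The regime call near a crossover molality is intrinsically uncertain;
  the `additive` label there is a statement about resolution, not physics.
* The encoded distance calibration is an anchored stand-in, adequate for
  shifts and differences; absolute distances inherit its ±0.01 Å anchor
  accuracy only near the anchors.
* Affected numbers and band parameters in the presets are plausible, not
  measured; conclusions about the real systems require the original (or
  new) spectra, for which the manifest-driven entry points
  (`read_series_manifest()`, `run_pipeline()`) are provided.
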