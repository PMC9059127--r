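# hdoshell

Quantitative difference-spectra analysis of solute-affected water from HDO
OD-stretch infrared spectra.

## The problem

How osmolytes such as trimethylglycine (TMG, betaine) and urea stabilize or
destabilize proteins is encoded in the water they share with the protein's
hydration shell. Dilute HDO in H2O is the cleanest spectroscopic probe of
that water: the OD stretching band (~2200-2750 cm^-1) is decoupled from the
OH bath and shifts with hydrogen-bond strength (Badger-Bauer: lower
wavenumber, stronger bond). `hdoshell` implements the quantitative
difference-spectra method on titration series of such spectra, for
spectroscopists and biophysical chemists who want the full chain — from
sample/reference absorbance pairs to hydration numbers, hydrogen-bond
energetics and O···O distance distributions — as tested, scriptable code.

## The method

For a single solute at molality *m*, with spectra on the molar-absorptivity
per-mole-of-water scale, the affected-water spectrum is

> ε_a(ν) = ε_b(ν) + (1 / N·M) · ∂ε(ν)/∂m |_(m→0)

with M the molar mass of water and N the **affected number** (moles of
water perturbed per mole of solute), selected as the smallest N whose
spectrum has no negative lobe beyond what spectral noise explains
(`estimate_N()`).

For a biomolecule (m) + osmolyte (o) solution the pair is treated as one
pseudo-solute: the **experimental** affected spectrum (count N_e) is
measured, the **synthetic** spectrum (N_s = n_m·N_m + n_o·N_o) is the
no-interaction construction from the pure components, and their difference

> D(ν) = N_e·ε_e(ν) − N_s·ε_s(ν),  N_double = N_e − N_s

isolates the **double-affected** water. N_double > 0 means extra,
bulk-drawn water cross-linking the two hydration spheres; N_double < 0
means water shared by overlapping spheres. The counts N_pe = N_e(β+1) and
N_ps = N_s(β+1) (β = m_o/m_m) compare the two constructions per mole of
biomolecule, with a Monte-Carlo uncertainty floor deciding when the
difference is significant. Band gravity centers (Δν^g) and the empirical
OD-wavenumber → O···O-distance transform (`distance_distribution()`,
anchored at 2505 cm^-1 ↔ 2.83 Å) turn the isolated contours into
hydrogen-bond energetics and distance populations.

Because no raw spectra are deposited for the motivating systems, the
package ships a forward generator (`generate_series()`, `preset_scenario()`)
that emulates the full measurement design — biomolecule constant, osmolyte
titrated, 4% D2O, 0.029 mm path, 25 °C, seeded noise — with known ground
truth, so every stage is testable end to end. Measured data enter through
the same interfaces via `read_series_manifest()`.

## Worked example

```r
library(hdoshell)

# single solute: urea titration (noiseless preset), affected number N
gen <- generate_series(preset_scenario("single_urea", noise_sd = 0))
fit <- fit_affected_water(gen$series)
summary(fit)
#> Affected water: urea
#>   N                 5.979 mol water / mol solute
#>   band max          2520.0 cm^-1
#>   gravity center    2520.0 cm^-1 (bulk 2503.9, shift +16.2)
#>   fit residual RMS  2.1e-15 (5 samples)

# two solutes: glycine (1 mol/kg) + urea at 1.5 mol/kg
fit_gly <- fit_affected_water(
  generate_series(preset_scenario("single_gly", noise_sd = 0))$series)
gen2 <- generate_series(preset_scenario("gly_urea"))
fd <- fit_double_affected(gen2$series$samples[[2]], fit_gly, fit,
                          mc_draws = 100)
fd
#> Double-affected water at m_o = 1.5 mol/kg (beta = 1.5)
#>   N_e = 4.669, N_s = 6.381, N_double = -1.712  [shared_overlap]
#>   N_pe = 11.67, N_ps = 15.95 per mol biomolecule

delta_nu_g(fd$double_spectrum, fit_gly$affected_spectrum)
#> +38.5 cm^-1
distance_distribution(fd$double_spectrum)
#> <distance_distribution> 257 points, 2.618-3.130 A, mode 2.882 A
```

Reading: the generator recovers the constructed urea affected number (truth
6) to 0.4%. In the two-solute system the experimental count sits below the
synthetic one (`shared_overlap`): glycine and urea hydration spheres share
water. The shared water's gravity center lies 38.5 cm^-1 *above* the
glycine-affected band — weaker hydrogen bonds — and its most probable O···O
distance (2.88 Å) is longer than the pure-water 2.83 Å, the signature of a
destabilizing osmolyte.

`run_pipeline(out_dir, preset = "gly_urea")` chains all stages and writes
`profile.tsv` (N_pe/N_ps/regime per molality), per-molality double spectra,
ΔP(R_OO) tables, and JSON reports carrying a config hash.

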