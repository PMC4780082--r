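# isovib

Isotope-edited FTIR difference spectroscopy and harmonic vibrational
analysis, in one R package.

## What problem this solves

BLUF-domain photoreceptors ("blue light sensor using flavin") switch
signaling states without any chemical change of their flavin chromophore:
the photoreaction rearranges hydrogen bonds around a conserved glutamine.
Whether that glutamine merely *rotates* or *tautomerises* to its imidic acid
(HO–C=N) form is the central mechanistic question, and infrared
spectroscopy answers it only indirectly — the carbonyl region
(1,600–1,700 cm⁻¹) is too congested to isolate the glutamine bands.

¹⁵N labelling at the glutamine side-chain nitrogen breaks the deadlock: an
amide C=O stretch shifts by only ~1 cm⁻¹ on labelling, the NH₂ scissor by
~8 cm⁻¹, but the C=N stretch of the imidic tautomer by 14–16 cm⁻¹. A
light-state band with a large ¹⁵N shift is therefore a fingerprint of
tautomerisation. `isovib` implements the full analysis chain this experiment
needs, for spectroscopists on the experimental side and computational
chemists on the assignment side:

* **Difference-spectrum pipeline** — unbiased least-squares amplitude
  scaling `s = Σab / Σa²` over a label-insensitive window
  (1,500–1,200 cm⁻¹), double differences `s·unlabelled − labelled`,
  magnitude band integrals, extremum normalization.
* **Constrained Lorentzian deconvolution** — the band model
  `y(x) = (2A/π)·w / (4(x−x_c)² + w²)` (area `A`, FWHM `w`), with band
  *pairs* of equal area magnitude (oscillator strength independent of
  labelling), fixed centers/areas, and one shared width, fitted by
  Levenberg–Marquardt with analytic Jacobian and seeded multistart. The
  canonical six-Lorentzian BLUF configuration has exactly 5 free
  parameters.
* **Harmonic analysis** — mass-weighted Hessian diagonalization with Eckart
  projection, per-atom isotope substitution, 0.965 frequency scaling, IR
  intensities from dipole derivatives, greedy maximum-overlap mode pairing
  across isotopomers, Wilson B-matrix and potential-energy-distribution
  (PED) tables over automatically generated internal coordinates, and
  combined shift + PED band assignment (C=O-like vs C=N-like vs ambiguous).
* **Spectrum simulation** — Lorentzian convolution of IR sticks (8 or
  7 cm⁻¹ FWHM), Gaussian convolution of UV–vis states on the energy axis
  (3,000 cm⁻¹ FWHM), computed difference and double-difference spectra.
* **Synthetic data** — seeded generators for paired unlabelled/labelled
  spectra with partial label incorporation (75% / 58%), noise and drift,
  and 9-atom valence-force-field surrogates of acetamide and its imidic
  acid (files always labelled `synthetic_`).

File formats: JCAMP-DX 4.24 subset and CSV for spectra; XYZ for geometries;
a GAMESS/Firefly-style punch dialect (`$HESS` / `$DIPDR`) and plain matrices
for Hessians and dipole derivatives.

## Worked example

```r
library(isovib)

# synthetic unlabelled / 15N-labelled difference-spectrum pair (75% incorporation)
pair <- synth_difference_pair(experiment_design(incorporation = 0.75, seed = 1))
dd <- double_difference(pair$unlabelled, pair$labelled)
cat(sprintf("scale factor s = %.3f\n", dd$meta$scale_factor))
#> scale factor s = 0.947

fit <- fit_bands(dd, bluf_dd_config(areas = c(0.004, 0.005, 0.003)), seed = 1)
summary(fit)
#> Constrained Lorentzian band fit
#>
#> Bands:
#>              label pair role      xc           A       w
#> 1 flavin_C4O_light    1  pos 1697.00  0.00400000 8.91516
#> 2 flavin_C4O_light    1  neg 1689.00 -0.00400000 8.91516
#> 3          dark_CO    2  pos 1660.00  0.00456047 8.91516
#> 4          dark_CO    2  neg 1667.00 -0.00456047 8.91516
#> 5        hidden_CN    3  pos 1696.09  0.00298256 8.91516
#> 6        hidden_CN    3  neg 1672.68 -0.00298256 8.91516
#>
#> Free parameters (5):
#>                        estimate  std_error
#> center.hidden_CN.pos 1.6961e+03 0.33531520
#> center.hidden_CN.neg 1.6727e+03 0.29482872
#> area.dark_CO         4.5605e-03 0.00020467
#> area.hidden_CN       2.9826e-03 0.00012895
#> fwhm                 8.9152e+00 0.23398521
#>
#> residual rms: 2.388e-05; converged: TRUE; best of 8 starts
```

The deconvolution finds a third, "hidden" band pair (here 1,696(+)/1,673(−)
cm⁻¹) that is not visible as separate extrema in the double difference —
its positive lobe cancels against the fixed 1,689(−) band — with the five
free parameters being the hidden pair's two centers, two pair areas, and
the shared width.

On the computational side, the isotope-shift/PED chain separates the
tautomers:

```r
a <- amide_surrogate()
nm   <- normal_modes(a$mol, a$hessian, scale = 0.965)
nm15 <- normal_modes(a$mol, a$hessian, iso = isotope_pattern(N3 = "15N"),
                     scale = 0.965)
shifts <- pair_modes(nm, nm15)
pt <- ped(nm, a$hessian, a$mol, a$coords)
subset(assign_band(pt, shifts), frequency > 1500)
#>   mode frequency    shift    dominant     label
#> 6    6      1680 6.58e-01    r(C1-O2)       C=O
#> 7    7      1595 8.00e+00 a(H5-N3-H6) ambiguous
```

The C=O-dominant mode at 1,680 cm⁻¹ shifts by only 0.7 cm⁻¹ (labelled
"C=O"); the NH₂ scissor at 1,595 cm⁻¹ shifts 8 cm⁻¹. Running the same chain
on `imidate_surrogate("pcm")` gives a C=N-dominant mode with a 16 cm⁻¹
shift, labelled "C=N".

## Package layout

| Area | Functions |
| --- | --- |
| Spectra & I/O | `ir_spectrum`, `read_spectrum`, `write_spectrum`, `resample`, `crop`, `wn_window` |
| Difference pipeline | `scale_factor`, `double_difference`, `band_integral`, `normalize_on_band` |
| Band model & fit | `lorentzian`, `model_eval`, `band_pair`, `single_band`, `fit_config`, `bluf_dd_config`, `count_free_parameters`, `fit_bands` (+ `summary`, `coef`, `predict`, `plot`, `residuals`, `simulate` methods) |
| Harmonic analysis | `molecule`, `read_xyz`, `read_hessian`, `normal_modes`, `isotope_pattern`, `ir_intensities`, `pair_modes`, `isotope_shift_table` |
| PED & assignment | `auto_internal_coords`, `b_matrix`, `ped`, `assign_band` |
| Simulation | `stick_spectrum`, `convolve_ir`, `convolve_uvvis`, `computed_difference`, `computed_double_difference`, `spectral_similarity` |
| Synthetic data | `experiment_design`, `synth_difference_pair`, `toy_force_field`, `toy_molecule`, `toy_co_oscillator`, `amide_surrogate`, `imidate_surrogate`, `fixture_suite` |

The methods vignette (`vignettes/isotope-edited-ftir.Rmd`) documents the
models, conventions (PED diagonal convention, Eckart projection, unit
system), calibration of the surrogate force fields, and known limitations.
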