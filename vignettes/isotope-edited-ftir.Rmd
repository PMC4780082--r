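---
title: "Isotope-edited FTIR difference spectroscopy: models, conventions and design choices"
author: "isovib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-edited FTIR difference spectroscopy: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isovib)
```

## The problem

Blue-light photoreceptors of the BLUF family signal without any chemical
change of their flavin chromophore: photoactivation rearranges the
hydrogen-bond network around a conserved glutamine next to the flavin. The
competing mechanistic proposals differ in whether that glutamine merely
rotates or tautomerises to its imidic acid form. Infrared difference
spectroscopy sees the rearrangement, but the 1,600–1,700 cm⁻¹ region is so
congested that the glutamine bands cannot be isolated directly.

Isotope editing resolves this. ¹⁵N substitution at the glutamine side-chain
amide nitrogen barely moves an amide C=O stretch (the nitrogen hardly
participates in that mode, ~1 cm⁻¹), shifts the NH₂ scissor moderately
(~8 cm⁻¹), but shifts the C=N stretch of the imidic tautomer strongly
(14–16 cm⁻¹, approaching the diatomic reduced-mass bound of ~26 cm⁻¹ only
when no other coordinate couples in). A band in the light-state spectrum with
a large ¹⁵N shift is therefore direct evidence of the imidic acid — of
tautomerisation.

The package implements the complete analysis chain around this idea:

1. **Experimental side** — scaling of paired unlabelled/labelled
   light-minus-dark difference spectra, construction of the
   *double-difference* spectrum, and its deconvolution with a constrained
   sum of Lorentzians.
2. **Computational side** — harmonic vibrational analysis of Cartesian
   Hessians with isotope substitution, mode pairing across isotopomers,
   infrared intensities, potential energy distributions (PED), and
   convolution of stick spectra into simulated IR and UV–vis traces.
3. **Synthetic data** — seeded generators for both sides, so every step is
   testable without access to an instrument or an electronic-structure code.

## Difference scaling and the double difference

Two samples never have identical path length and concentration, so before
subtraction the unlabelled difference spectrum $a(\tilde\nu)$ is scaled onto
the labelled one $b(\tilde\nu)$ by the unbiased least-squares factor

$$ s = \arg\min_s \sum_{w} (s\,a - b)^2 = \frac{\sum_w a b}{\sum_w a^2}, $$

computed over a window (default 1,500–1,200 cm⁻¹) in which isotope labelling
has no appreciable effect. No additive offset is fitted: difference spectra
are already baseline-referenced, and an offset would absorb genuine broad
signals. The double difference is then $s\,a - b$ on the common grid — the
grid of the labelled spectrum restricted to the overlap, a deterministic and
declared choice. Linear interpolation (never splines) is used for
resampling, because spline overshoot between points would survive the
subtraction as spurious bands, which is worse than the slight smoothing
linear interpolation causes at 2 cm⁻¹ instrument resolution.

Under this convention ("unlabelled minus labelled") a band of the unlabelled
species appears positive and its downshifted labelled counterpart negative,
so a dark-state difference band produces a (−, +) pattern in descending
wavenumber order and a light-state band a (+, −) pattern.

Band intensities are compared with `band_integral()`, a trapezoidal integral
of $|\Delta A|$: signed integrals of difference bands largely cancel, while
the magnitude integral tracks what a spectroscopist means by "band
intensity" (e.g. amide I intensity, 1,695–1,615 cm⁻¹, after normalizing two
proteins on their flavin C₄=O band with `normalize_on_band()`).

## The constrained Lorentzian band model

Each isotope-affected difference band contributes a *pair* of Lorentzians of
opposite sign. The package uses the area parameterization

$$ y(x) = \frac{2A}{\pi}\,\frac{w}{4(x - x_c)^2 + w^2}, $$

whose integral over the real line is exactly $A$ and whose peak height is
$2A/(\pi w)$; $w$ is the FWHM. The area form makes the central physical
constraint — *oscillator strength independent of labelling*, i.e. the
positive and negative band of a pair have equal area magnitude — an exact
statement about one parameter.

Constraints are applied by reparameterization, never by penalty: a unity
pair carries one area parameter with fixed signs, fixed centers and areas
are simply excluded from the parameter vector, and a shared FWHM is one
parameter for all bands. `count_free_parameters()` implements the resulting
bookkeeping: $3n$ raw parameters minus one per fixed center, per fixed area,
per unity pair, and $n-1$ when all $n$ bands share a width. The canonical
BLUF configuration (`bluf_dd_config()`) — six Lorentzians, four fixed
centers at 1,697/1,689 and 1,667/1,660 cm⁻¹, the 1,697-pair area fixed,
three unity ratios, one shared width — has exactly five free parameters: the
two hidden-pair centers, two pair areas, and the width.

```{r}
cfg <- bluf_dd_config()
count_free_parameters(cfg)
```

### Optimizer

`fit_bands()` minimizes the unweighted residual sum of squares (uniform
weighting; difference-spectrum noise is close to homoscedastic across a
50 cm⁻¹ window) by Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
analytic Jacobian of the Lorentzian sum. Because the hidden pair overlaps
the fixed bands, a single start can stall in a local minimum; the fit
therefore runs a seeded multistart (default 8 starts: the nominal values
plus perturbations of ±3 cm⁻¹ on free centers, ±50% on areas, up to +50% on
widths) and keeps the best. Pair areas are bounded below by zero — a pair
whose area reaches zero has dropped out of the model, which also gives the
nested-model property that a three-pair fit can never fit worse than the
two-pair fit it contains. Width parameters are bounded below by
0.01 cm⁻¹. Convergence tolerances are `ftol = ptol = 1e-14`, tight enough
that noiseless synthetic data are recovered to machine-level accuracy.

Degenerate configurations (zero free parameters, fewer points than
parameters) are errors, not warnings. Standard errors come from the usual
linearized covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum.

### Parameter recovery

On noiseless data generated from the three-pair model itself, the fit
recovers the hidden centers and shared width exactly (residual rms at
machine precision), from starts perturbed well beyond the multistart
envelope; with 1% peak-level Gaussian noise the hidden-pair centers are
unbiased to well under 0.2 cm⁻¹. Both properties are exercised in the test
suite on a 0.5 cm⁻¹ grid over 1,650–1,700 cm⁻¹ (101 points).

## Harmonic analysis conventions

* **Units.** Hessians in hartree/bohr², geometries in Å, masses in amu,
  frequencies in cm⁻¹, IR intensities in km/mol. The conversion constant is
  5140.487 cm⁻¹ per $\sqrt{E_h\,a_0^{-2}\,\mathrm{amu}^{-1}}$ and
  974.880 km/mol per $(e\,\mathrm{amu}^{-1/2})^2$, both from CODATA 2018
  values, centralized in one internal table.
* **Eckart projection.** The six rigid-body directions (five for linear
  molecules — detected by a rank drop of the rotational vectors) are built
  explicitly at the input geometry in mass-weighted coordinates,
  orthonormalized by QR, and projected out of the mass-weighted Hessian.
  The test suite checks that exactly six near-zero frequencies remain
  (|ν̃| < 1 cm⁻¹).
* **Imaginary modes** are reported as negative frequencies and excluded from
  isotopomer pairing by default, so Hessians from non-stationary geometries
  cannot silently corrupt shift tables.
* **Frequency scaling.** The empirical factor 0.965 appropriate for
  B3LYP/6-31G(d,p)-grade Hessians of hydrogen-bonded amides is applied via
  the `scale` argument; unscaled frequencies are always retained alongside.
  Scaling commutes with pairing (shifts simply scale), which is asserted as
  a property test.
* **Masses.** Defaults are most-abundant-isotope masses (¹⁵N =
  15.0001089 amu, ²H = 2.0141018 amu); any atom can be overridden per
  `isotope_pattern()`, so labelling only the side-chain nitrogen, backbone
  nitrogens too, or deuterating water molecules are all expressible.
* **Sign convention.** Each mass-weighted eigenvector is flipped so its
  largest-magnitude component is positive — deterministic output for
  testing and file round trips.

### Pairing modes across isotopomers

`pair_modes()` assigns modes of two isotopomers greedily by decreasing
absolute overlap of their mass-weighted displacement vectors, computed in
the metric of the reference (unlabelled) isotopomer; at Δm = 1 amu the
metric choice is numerically immaterial, and a single metric keeps overlaps
symmetric and the algorithm simple. Each mode is used at most once. When the
best and second-best candidate overlap within 0.05 the pairing is flagged
ambiguous with a warning naming both candidates — never silently resolved.

### PED convention

Several PED conventions exist; the package uses the diagonal-element
convention and states it. With $B$ the Wilson matrix of the (redundant)
internal coordinate set, $A = M^{-1}B^\top (B M^{-1} B^\top)^+$,
$F = A^\top H A$ the internal force-constant matrix, and $s_i = B x_i$ the
internal displacement of mode $i$, the contribution of coordinate $q_s$ is

$$ \mathrm{PED}_{is} \propto F_{ss}\, s_{si}^2, $$

normalized over $s$ within each mode, so every row sums to one and entries
lie in $[0, 1]$. Off-diagonal coupling terms are *not* folded into the
entries; instead the ratio of the diagonal sum to the full $\lambda_i$ is
reported per mode (`diag_fraction`) as a coupling diagnostic. This is the
common default convention; published PED tables computed with
coupling-partitioned conventions will differ in detail, which is the main
expected source of small numerical differences when comparing against
external results.

Redundant coordinates are retained as generated (no delocalized-coordinate
reduction); the pseudo-inverse handles the redundancy, and a rank check of
$B M^{-1/2}$ against the vibrational count fails loudly — naming the missing
coordinate type — rather than producing silently wrong tables. Internal
coordinates are generated automatically: bonds by the covalent-radius
criterion $r < 1.3\,(r_A + r_B)$ (Cordero radii, factor configurable),
angles over all bonded triples (near-linear ones above 175° dropped with a
warning), torsions over all bonded quadruples.

### Assignment rules

`assign_band()` labels a mode "C=O" only when *both* lines of evidence
agree: shift magnitude ≤ 3 cm⁻¹ *and* a C–O-stretch-dominant PED; "C=N"
requires shift ≥ 10 cm⁻¹ *and* C–N dominance. Everything between the
thresholds, and every conflict between PED and shift, is labelled
"ambiguous". The thresholds (3 and 10 cm⁻¹) sit on either side of the
observed gap between amide C=O shifts (≈1 cm⁻¹) and imidic C=N shifts
(≥13 cm⁻¹) and are configurable.

## Spectrum simulation

Computed stick spectra are convolved with area-normalized Lorentzians
(default FWHM 8 cm⁻¹; 7 cm⁻¹ is conventional for double-difference
comparisons) on a 1 cm⁻¹ grid over 1,800–1,200 cm⁻¹. UV–vis states are
convolved with Gaussians of 3,000 cm⁻¹ FWHM *on the energy axis* — the FWHM
is stated in cm⁻¹, so applying it in wavelength would be dimensionally
inconsistent — and then evaluated on a nm grid, without a Jacobian
reweighting, so a single state peaks exactly at $10^7/E_0$ nm. The computed
double difference $(L_u - D_u) - (L_l - D_l)$ integrates to approximately
zero whenever intensities are isotope-independent — the same physical
assumption as the unity area-ratio constraint of the band fit, checked as a
property test.

## The synthetic-data generator

`synth_difference_pair()` emulates the structure of a real isotope-editing
experiment on a BLUF protein:

* difference bands as Lorentzian pairs (dark negative, light positive) with
  the band set given in `experiment_design()`: the flavin C₄=O difference
  band (dark 1,710, light 1,697 cm⁻¹), the glutamine dark-state C=O at
  1,667 cm⁻¹ whose light-state partner is the imidic C=N at 1,691 cm⁻¹,
  amide I bands around 1,641/1,623 cm⁻¹, and label-insensitive fingerprint
  bands below 1,500 cm⁻¹ that anchor the scaling step;
* **partial incorporation** as a linear mixture: the labelled trace is
  $(1-p)$ times the unshifted band set plus $p$ times the shifted set —
  dilute, non-interacting isotopomers add linearly in absorbance. Default
  $p = 0.75$ (a well-labelled sample); $p = 0.58$ with reduced amide I
  amplitude emulates a second protein with lower incorporation and smaller
  conformational change;
* white Gaussian noise (default sd 1 × 10⁻⁵ absorbance, a documented
  estimate of the sample-to-sample variation of a well-averaged rapid-scan
  difference measurement — the true magnitude is only known graphically) and
  an optional low-order polynomial drift.

What it does **not** emulate: Voigt/temperature-dependent line shapes,
correlated (1/f) instrument noise, atmospheric water-vapor lines, or the
region-specific drift that can render parts of a real spectrum unusable.
Passing tests on this generator therefore demonstrate correctness of the
*analysis*, not robustness to every instrumental pathology.

```{r}
pair <- synth_difference_pair(experiment_design(incorporation = 0.75))
dd <- double_difference(pair$unlabelled, pair$labelled)
round(dd$meta$scale_factor, 3)
```

## Surrogate molecules and their calibration

Where the analysis chain would consume first-principles Hessians, the
package provides full 9-atom valence-force-field surrogates of acetamide
and its Z-Z imidic acid (`amide_surrogate()`, `imidate_surrogate()`),
assembled as $H = B^\top F B$ at a standard planar geometry — exactly
positive semidefinite with an exact six-dimensional rigid-body null space —
plus bond-dipole derivatives. Most force constants are standard valence
values (C–H 4.8, N–H 6.3, O–H 7.2 mdyn/Å, HCH bends 0.52 mdyn·Å/rad², …).
The three constants that *place* the diagnostic bands — the C=O (or C=N)
stretch constant, the HNH bend constant, and one stretch–bend coupling —
were fixed once by a deterministic Nelder–Mead solve against the documented
target positions and ¹⁵N shifts (amide C=O near 1,680 cm⁻¹ shifting
~1 cm⁻¹, NH₂ scissor near 1,595 cm⁻¹ shifting ~8 cm⁻¹; imidic C=N at
1,690 cm⁻¹ shifting 16 cm⁻¹ for the dielectric-environment variant and
1,675 cm⁻¹ shifting 14 cm⁻¹ for the hydrogen-bonded variant), and are
frozen in the source with the calibration machinery documented here.

Because the shift targets enter the calibration, the end-to-end tests on
these surrogates are *consistency* checks — that the full Cartesian chain
(mass-weighting, Eckart projection, isotopomer pairing, PED, assignment)
reproduces from the Hessian files what the calibration imposed through a
reduced model — together with genuine physics the calibration did not
impose: the C=O shift is *not* calibrated (it emerges at ~0.7 cm⁻¹ from the
weak coupling to the scissor), the coupled C=N shift stays well below the
~26 cm⁻¹ diatomic reduced-mass bound, and the PED dominance patterns that
drive the assignment are emergent. Files written by `fixture_suite()` carry
the `synthetic_` prefix to make their provenance unmistakable.

```{r}
a <- amide_surrogate()
nm <- normal_modes(a$mol, a$hessian, scale = 0.965)
nm15 <- normal_modes(a$mol, a$hessian, iso = isotope_pattern(N3 = "15N"),
                     scale = 0.965)
pr <- pair_modes(nm, nm15)
pt <- ped(nm, a$hessian, a$mol, a$coords)
head(assign_band(pt, pr))
```

## Numerical choices and degenerate inputs

* Windows are inclusive on both bounds, matching the way spectral ranges
  are quoted ("1,650–1,700 cm⁻¹").
* Spectra are stored in descending wavenumber (FTIR display convention);
  readers accept either direction and record the original order.
* `scale_factor()` on a window where the reference has zero power, crops
  that retain fewer than two points, empty stick spectra, missing dipole
  derivatives, non-symmetric Hessians beyond 10⁻⁸ relative, and
  rank-deficient internal-coordinate sets are all explicit errors (or, for
  the empty stick case, a warning with a zero spectrum).
* Zero modes are identified by |ν̃| < 1 cm⁻¹; mode-pairing ambiguity by an
  overlap gap < 0.05.
* All random elements (multistart perturbations, synthetic noise) are
  seeded; generators are bit-reproducible for a given seed.

## Problem sizes

The shipped tests and the acceptance script run at the scale of the method
itself, which is small: 101-point fit grids (0.5 cm⁻¹ over
1,650–1,700 cm⁻¹), 551-point synthetic spectra (1 cm⁻¹ over
1,750–1,200 cm⁻¹), 9-atom surrogate Hessians (27 × 27), 40-replicate
noise-recovery studies. The full suite completes in well under a minute.

## Known limitations

* The band model is Lorentzian-only by design; no Voigt or Gaussian IR line
  shapes, and no automatic model selection beyond reporting nested-fit
  residuals.
* No electronic-structure computation: Hessians, dipole derivatives and
  excited-state stick spectra are consumed, not produced. The surrogate
  force fields are stand-ins, not substitutes for quantum-chemical accuracy;
  only their isotope-shift *contrast* is meaningful, not absolute
  frequencies.
* No anharmonic corrections; the 0.965 scaling absorbs them only on
  average.
* Kinetic (time-resolved) global analysis is out of scope; homogeneous
  decay can be checked only by comparing normalized band integrals between
  time windows.
* The PED uses the diagonal convention; coupling-partitioned PED tables
  from other software will differ in the decimals.
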