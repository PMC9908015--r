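---
title: "Models and methods behind plasmonruler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plasmonruler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmonruler)
```

## The sensing principle

plasmonruler models and analyses a tethered-nanoparticle plasmon-ruler
aptasensor for endotoxin (bacterial lipopolysaccharide, LPS). An 80-nm
gold nanoparticle (AuNP) is tied to a gold nanofilm (AuNF) by a single
66-nt ssDNA aptamer construct (RD1): a 36-nt endotoxin-binding core
flanked by two 15-nt extension arms, coupled to the film by an amino/EDC-NHS
linkage and to the particle by a thiol. Unbound, the construct is a
flexible polymer and the particle hovers relatively high; when the core
folds around an endotoxin molecule it collapses into a compact rigid
complex (2–4 nm), pulling the particle closer to the film. Because the
film-coupled plasmon resonance of the particle depends steeply on the
gap, the scattered colour shifts red as the gap shrinks. The observable
is the RG ratio — scattered intensity at a red wavelength over a green
wavelength — measured either on the summed spectrum of many particles
(ensemble mode) or per particle in dark-field colour images
(single-particle mode).

The package implements the full computational chain: (1) Monte Carlo
sampling of the tether conformations, (2) inverse-Boltzmann conversion of
the height histogram into a potential of mean force, (3) overdamped
Brownian dynamics of the particle height, (4) a gap-to-spectrum model
with RG readout, (5) the ensemble calibration/LOD/statistics pipeline,
(6) single-particle image analysis, (7) Sauerbrey analysis of quartz
crystal microbalance (QCM) traces, and (8) synthetic-data generators that
make every stage testable with known ground truth.

## Tether model and Monte Carlo sampling

The tether is a composite worm-like chain, discretised at the Kuhn scale
into a freely jointed chain: a flexible segment of contour length
$L_c$ and Kuhn length $b$ becomes $\max(1,\mathrm{round}(L_c/b))$ links of
equal length (preserving $L_c$); a rigid segment is a single rod. Link
directions are isotropic. Since every boundary condition acts on $z$
only, and the $z$-component of an isotropic unit vector is uniform on
$[-1,1]$, the sampler draws only $z$-components — an exact marginalisation,
not an approximation.

Geometry defaults, chosen once:

* ssDNA rise 0.63 nm/nt, so the 66-nt construct has 41.58 nm of ssDNA
  contour.
* ssDNA Kuhn length **3.0 nm**. Values quoted for ssDNA span roughly
  1.2–6 nm depending on ionic strength; within that range we fixed the
  value that reproduces the published simulated mean heights
  (7.14 nm unbound, 5.40 nm bound) to within the stated ±1 nm. Stiffer
  (larger $b$) chains extend further; 1.5 nm, for example, yields an
  unbound mean near 5.4 nm, well below the published 7.14 nm.
* End linkers (the HS-C11-EG6 SAM tether plus EDC-NHS bond on the film
  side, the thiol anchor on the particle side) are each one rigid
  1.25-nm rod: short SAM-scale linkers are nearly fully extended.
* In the bound state the entire 36-nt core is replaced by one rigid
  segment of the complex length (2–4 nm); no residue-level structure of
  the fold is available, so the maximal-collapse reading is used.

Boundary conditions: every chain node satisfies $z \ge 0$ (the film is
impenetrable), chains are resampled on rejection until the requested
count is reached, and the particle is attached at its lowest pole with
rotation ignored — so the reported gap equals the tether's end-to-end
$z$-extension and the sphere–film constraint coincides with the terminal
node constraint. Chain–particle excluded volume is ignored (the standard
tethered-particle-motion simplification; the node–film and sphere–film
constraints dominate). The published height values (< 10 nm) are only
consistent with reading "z-height" as this gap, not as the
particle-centre height.

With these choices, $10^5$ chains give an unbound mean of ≈ 7.4 nm and a
bound mean (pooled over complex lengths 2–4 nm) of ≈ 5.4 nm.

## Potential of mean force

`invert_boltzmann()` converts the height histogram $p(z)$ (default bin
width 0.25 nm — 30+ bins across the relevant range without starving
counts at $10^4$–$10^5$ samples) into $E(z) = -\ln p(z)$ in units of kT,
shifted to $\min E = 0$. Bins with zero observed probability get a finite
capped energy, $E_{\max,\text{obs}} + 5$ kT, so the force field stays
finite; the Boltzmann re-weighted density then differs from the input
only by the (exponentially small) leaked mass on those bins. The force
$F = -dE/dz$ uses centred finite differences, one-sided at the ends.
`force_at()` interpolates linearly; above the last bin the force is
continued linearly, below the first bin the film's reflecting wall takes
over.

## Brownian dynamics

`simulate_trajectory()` integrates the overdamped Langevin equation with
the Euler–Maruyama scheme,
$z' = z + \tfrac{D}{kT} F(z)\,\Delta t + \sqrt{2 D \Delta t}\,\xi$,
with $\Delta t = 10^{-8}$ s by default and
$D = kT / (6 \pi \eta R)$ from Stokes–Einstein
(≈ 6.1 × 10⁻¹² m²/s for an 80-nm sphere in water at 298 K,
η = 8.9 × 10⁻⁴ Pa s). Design choices:

* Reflecting boundaries at the film ($z = 0$) and at the upper edge of
  the profile's sampled support — the potential of mean force is only
  defined where the equilibrium ensemble visited, and a flat profile
  would otherwise let the particle escape upward.
* No height-hindered diffusion correction: a $z$-dependent mobility
  rescales time but not the equilibrium distribution, and only
  equilibrium statistics feed the optical signal.
* The initial height is drawn from the equilibrium density implied by
  the profile, removing burn-in sensitivity.
* The integrator aborts if the rms step exceeds 5 bin widths.

The module's central property — tested, not assumed — is equilibrium
consistency: dynamics in the inverted potential reproduce the Monte
Carlo histogram (Kolmogorov–Smirnov distance ≤ 0.05 at $10^4$ chains /
$10^6$ steps).

## Gap-to-spectrum surrogate

Full electromagnetic (boundary-element) simulation of the coupled
particle–film system is out of scope here. `scattering_spectrum_at_gap()`
uses a two-mode plasmon-ruler surrogate instead: a fixed "green"
particle mode near 600 nm and a gap-coupled "red" mode that sits near
720 nm at contact, whose amplitude decays as
$e^{-g/d}$ and whose centre relaxes toward an uncoupled position
(650 nm) as the gap $g$ opens; the green amplitude recovers as
$1 - a\,e^{-g/d}$. Both modes are unit-peak Lorentzians (FWHM 70 nm).
The two free constants were calibrated once so that the bound/unbound
tether ensembles produce a simulated RG increase of ≈ 1.24 → ≈ 1.56 at
720/600 nm, the scale of the measured ensemble shift: $d = 23.5$ nm,
$a = 0.77$. These are surrogate constants shipped in
`plasmon_params()`, not electromagnetic results; everything downstream
uses only the qualitative contracts (RG strictly decreasing in gap, RG
invariant to intensity rescaling, linear time averaging), which the
surrogate preserves by construction.

Two RG wavelength conventions coexist deliberately: simulated spectra
are read at 720/600 nm (the surrogate's peaks), measured spectra at
709/585 nm (the empirically better instrument wavelengths). Both are
explicit arguments of `rg_ratio()`; nothing cross-calibrates the two
scales.

## Ensemble analysis

`correct_spectrum()` applies (raw − background)/excitation with
clipping at zero; the RG of a corrected spectrum is invariant to any
multiplicative rescaling of the excitation. `fit_calibration()`
regresses replicate-mean RG on the **natural logarithm** of
concentration. The log base matters: the published line
(slope 0.106, intercept 0.902) evaluated at 500 EU/ml gives 1.561 under
ln — within 0.2 % of the measured 1.563 — whereas a base-10 reading does
not; ln is therefore the fit definition (with `log_base` exposed).
Blanks (0 EU/ml) are excluded from the fit and kept for significance
testing. `estimate_lod()` reports the detection limit the way a
bracketing design supports it: the pair (highest level not significantly
different from blank, lowest significantly different level), requiring
monotone significance flags; flags can be supplied or derived from
replicate RG values by pooled two-sided t tests at α = 0.05.
`compare_groups()` wraps Student's t (pooled by default, Welch by flag)
for two groups and one-way ANOVA for three or more. `eu_to_ng()` encodes
the preparation-specific activity equivalence 10 EU = 1 ng.

## Single-particle analysis

`detect_particles()` finds diffraction-limited spots as local maxima of
the Gaussian-smoothed (σ = 1 px) channel-summed image. The threshold is
`median + k·σ_bg`, where σ_bg is a robust upper-quantile estimate
(90th percentile minus median, Gaussian-scaled) of the **raw** per-pixel
background noise — robust both to the skew of zero-clipped camera noise
and to a sparse bright-spot population, and referenced to the raw image
so the smoothing gain (≈ 3.5× for these kernel sizes) acts as a
false-positive safety margin. The default k = 3 therefore sits ≈ 10
smoothed-noise sigmas above background: blank frames essentially never
fire, while spots at raw peak SNR 10 are recovered with ≥ 95 %
precision and recall. Non-maximum suppression enforces a minimum
separation (default 5 px); photometry uses a 3-px disk aperture against
the median of a 2-px annulus (a diffraction-limited spot at ×40 on a
colour camera spans a few pixels), and detections whose annulus leaves
the frame are dropped. Per-particle RG is the background-subtracted mean
red over mean green — camera channels used as-is, no spectral unmixing,
and invariant to global gain and offset by construction. Coordinates
are 0-based with pixel centres at integers. Before/after frames are
independent particle sets (no tracking); `population_shift()` compares
them with the ensemble t test. `nn_spacing()` gives nearest-neighbour
statistics for spacing characterisation.

## QCM analysis

`sauerbrey_mass()` converts a frequency-drop magnitude to areal mass,
$m = C\,\Delta f / n$, with crystal defaults of a 5-MHz fundamental,
$C$ = 17.7 ng cm⁻² Hz⁻¹ and a third-overtone raw (un-normalised)
frequency. The instrument constants are not published for this
experiment; this is the unique standard combination under which the
published 33-Hz aptamer immobilisation drop reproduces the published
5.5 × 10¹² molecules/cm² given the RD1 molecular weight, and all four
constants are explicit configuration. `sequence_mw()` sums per-residue
monophosphate masses with the 5′/3′-OH end correction plus a documented
terminal-modification table (amino-C6 ≈ 179.2, thiol-C6 ≈ 196.2 g/mol,
hexyl linkers through an added phosphodiester). The chain
Δf → mass → `surface_density()` is linear in Δf and inverse-linear in
MW; `fraction_percent()` expresses coupling efficiencies and bound
fractions. `fit_binding_slope()` fits an OLS line over a labelled trace
interval in Hz/min. Viscoelastic films violate Sauerbrey; a rigidity
warning is emitted when a supplied dissipation/frequency ratio exceeds a
configurable bound, but no viscoelastic model is attempted.

## Synthetic data and what passing tests mean

Each generator emulates one experimental data type with known ground
truth attached (`ground_truth()`), and each is *closed* under its
matching analyser — `analyze(generate(θ))` recovers θ within stated
tolerances — which is the master property of the test suite:

* `synth_spectrum()`: two Lorentzians with the red amplitude solved in
  closed form so the noiseless RG equals the target exactly.
* `synth_titration()`: RG = slope·ln(C) + intercept + N(0, σ); the
  default σ = 0.015 matches the spread of published replicate SDs
  (0.008–0.03), so power statements from simulations are realistic.
* `synth_darkfield_image()`: sequential hard-core (Matérn-thinning
  style) particle placement — the published fields are well separated
  with no aggregation — calibrated once (exclusion radius 0.62 s,
  intensity 0.37/s² in the border-reduced area) so the realised mean
  nearest-neighbour spacing lands on the 3.6-µm target; Gaussian PSF
  spots whose channel amplitudes realise each particle's drawn RG;
  Poisson photon noise plus Gaussian read noise. A 1.5-µm border
  keep-out keeps every true spot fully measurable.
* `synth_qcm_trace()`: each adsorption step delivers its Δf through an
  exponential settling confined to the first quarter of the step
  (rescaled to reach Δf exactly), then drifts linearly; the annotated
  interval is the post-settling portion, so a noiseless fitted slope
  equals the generating slope exactly, and with drift-free steps the
  cumulative end-of-trace drop is exactly ΣΔf. Step Δf values exclude
  drift by definition.

What passing does **not** show: the generators share their functional
forms with the analysers (Lorentzian peaks, ln-linear calibration,
Gaussian PSF), so closure demonstrates correctness of the
implementation, not robustness to model mismatch in real spectra
(asymmetric lineshapes, film roughness), real images (Bayer demosaicing,
chromatic aberration, white balance) or real QCM traces (viscoelastic
response). The published absolute spectra, the measured single-particle
RG distributions and the specificity/regeneration/stability panels are
experimental data without a public record and are covered only by the
structural property suites, never reproduced numerically.

## Problem sizes and numerical conventions

Default problem sizes are chosen for interactive desk use and are the
ones the documentation and examples report: $10^5$ Monte Carlo chains
(seconds), $10^6$ Brownian-dynamics steps (10 ms simulated, under a
second), 100-seed recovery ensembles for calibration and slope
statistics, and ≈ 100-particle synthetic fields. Every stochastic entry
point requires an explicit seed and is bit-reproducible under it.
Energies are kept in kT throughout (temperature stored only for unit
conversion); lengths in nm, times in s, wavelengths in nm, masses in
ng/cm², concentrations in EU/ml with the 10 EU/ng conversion explicit.

## Known limitations

* The scattering surrogate is qualitative; absolute cross sections,
  particle-size dispersion and film roughness are not modelled.
* Only the gap coordinate is simulated — no x,y statistics, no particle
  rotation, no chain–sphere excluded volume.
* The two RG scales (spectrometer vs colour camera) are treated as
  distinct; nothing in the package converts one into the other.
* Sauerbrey analysis assumes a rigid film; the dissipation check warns
  but does not correct.
* The LOD is a bracketing statement between tested concentrations, not
  a 3σ/IUPAC extrapolation.
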