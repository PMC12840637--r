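---
title: "Biophysical profiling of lens epithelial cells: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical profiling of lens epithelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensmech)
```

# Scope

`lensmech` quantifies three biophysical readouts of cultured cells — here,
human lens epithelial cells (HLECs) under control, high-glucose ("model")
and drug-rescue (gigantol) conditions:

1. **Morphology** from AFM topography: cell height from a cross-section
   profile, and Ra/Rq surface roughness of a local membrane region.
2. **Stiffness** from AFM force spectroscopy: the Young's modulus via the
   spherical Hertz contact model.
3. **Membrane fluidity** from Raman spectroscopy: the lipid-chain order
   parameters $S_l$ and $S_t$ from band-height ratios.

Because no instrument data are deposited alongside the study this package
emulates, every stage is exercised against a first-class synthetic-data
module whose generators invert the analysis equations, so pipeline recovery
is exact in the noiseless limit and degrades gracefully with the stated
noise.

# Models and their assumptions

## Roughness (Ra, Rq)

Over a rectangular region of $N$ height samples $Z_i$ (nm), after local
detrending,

$$R_a = \frac{1}{N}\sum_{j=1}^{N} |Z_j - \bar Z|, \qquad
  R_q = \sqrt{\frac{1}{N}\sum_{i=1}^{N} (Z_i - \bar Z)^2}.$$

Deviations are taken about the region mean: the literal arithmetic-mean
formula without centering or absolute values is identically ~0 on flattened
data and cannot produce published roughness tables, and the root-mean-square
form is exactly the (population) standard deviation of the region — the
quantity roughness is conventionally computed from. $R_q \ge R_a$ always
(power-mean inequality); for a Gaussian surface texture of SD $\sigma$,
$E[R_a] = \sigma\sqrt{2/\pi}$ (half-normal mean) and $E[R_q] = \sigma$,
which the test suite uses as an analytic oracle.

The region is detrended with a best-fit plane by default (`detrend = 1`),
which strips residual cell-body curvature and scanner tilt; `detrend = 0`
(mean removal only) is exposed because whether published values were
computed on raw or plane-fit regions is generally not stated.

## Cell height

A cross-section profile through the cell is interpolated bilinearly from
the (order-1 flattened) height map. The substrate level is the median of
the lowest 20% of profile samples — robust to roughness on the substrate —
and height is the profile maximum minus that level, reported in µm.
The profile must span substrate on both sides of the cell.

## Hertz contact model

For a spherical indenter of radius $R$ at indentation $\delta$,

$$F(\delta) = \tfrac{4}{3}\sqrt{R}\,E_r\,\delta^{3/2}, \qquad
  \frac{1}{E_r} = \frac{1-\nu_t^2}{E_t} + \frac{1-\nu_s^2}{E_s},$$

with $E_r$ the reduced modulus. The tip is treated as rigid
($E_t \to \infty$), the universal convention for stiff AFM probes on soft
cells, so $E_s = E_r(1-\nu_s^2)$; cells are assumed incompressible
($\nu_s = 0.5$, so $E_s = 0.75\,E_r$). All arithmetic is done in nm / nN /
kPa ($1\ \mathrm{kPa\,nm^2} = 10^{-6}$ nN).

**Contact-point estimation.** The raw record's indentation axis is a piezo
position; the true tip–sample contact lies somewhere inside the ramp.
Detection thresholds the force at `median + 3·MAD` of the first 20% of
samples, demanding 5 consecutive samples above threshold. Robust statistics
matter here: the 20% window may contain the contact itself, and mean/SD
statistics would inflate the threshold. A threshold crossing necessarily
fires *after* true contact (the force has to climb out of the noise), so the
subsequent least-squares refinement searches the contact point from the
start of the ramp up to 10 samples past the detection — an asymmetric
window. Because the model is linear in $E_r$, the modulus is profiled out in
closed form for each candidate contact point and only the contact point is
searched numerically (coarse grid, then golden-section); this removes any
need for multi-start initialisation and recovers generator moduli to
better than $10^{-4}$ relative at zero noise and to <1% bias at 0.05 nN
noise.

**Quality flags.** Fits are flagged and excluded from group summaries when
$E_r$ lands on its bounds ([0.01, 10^4] kPa) or when the mean squared
residual exceeds 25× the curve's noise variance. The noise variance is
estimated from second differences of the force signal (smooth trends cancel;
white noise of SD $\sigma$ leaves second differences of SD
$\sigma\sqrt{6}$), which flags structurally non-Hertzian (e.g. linear) data
even when it is noiseless.

## Membrane-fluidity order parameters

After baseline correction, band heights are read as windowed maxima
(half-window 8 cm⁻¹) and combined as

$$S_l = \frac{I_{2890}/I_{2850} - 0.7}{1.5}, \qquad
  S_t = \frac{I_{1130}/I_{1090}}{1.77}.$$

$S_l$ (lateral order) tracks inter-chain packing through the CH₂ stretching
pair; $S_t$ (trans order) tracks the trans/gauche conformer balance of the
acyl-chain C–C skeleton. Higher values mean a more ordered, less fluid
membrane. The constants 0.7, 1.5 and 1.77 are literature calibration
constants and are treated as fixed. Both parameters are ratios of heights,
hence exactly invariant to intensity rescaling, and robust (<1% change) to
global wavenumber shifts up to 3 cm⁻¹ given the 8 cm⁻¹ windows.

The band-naming in the source literature is not fully consistent (2880 vs
2890; "–C–C– trans" vs "–C=C–" for the 1130 cm⁻¹ band); the package
canonicalises to the pairs the defining equations use — 2890/2850 and
1130/1090 — and every center is configurable via `default_bands()`.

**Baseline correction** uses asymmetric least squares (a Whittaker smoother
with asymmetric weights $p$ above / $1-p$ below the current estimate). The
defaults are `lam = 1e11`, `p = 0.001`, 10 iterations, and the stiffness is
deliberately high: the smoother's length scale grows as $\lambda^{1/4}$
grid points, and on dense spectrometer grids (0.5–1 cm⁻¹/point) it must
exceed the width of overlapping band *clusters* (~100 cm⁻¹ in the CH
stretching region), otherwise the baseline climbs into the cluster's shared
Lorentzian tails and biases every height ratio (with the commonly quoted
`lam = 1e5` the recovered $S_l$ is ~7% high on this package's own
fixtures). The cost of the stiff default is that strongly curved
backgrounds are tracked only approximately; linear baselines (the dominant
effect for these spectra) lie in the penalty's null space and are removed
exactly.

## Group statistics

Summaries are mean ± sample SD (n−1). Pairwise comparisons use the unpaired
two-tailed Student's t-test (pooled variance; Welch optional) following the
figure scheme: each group vs control, and rescue vs model; a one-way ANOVA
spans all groups. Significance tiers are 0.05 and 0.01. No multiple-testing
correction is applied by default, matching the source analysis; a
Bonferroni switch exists. Variation rates are
$100\,(\bar x_{cmp} - \bar x_{ref})/\bar x_{ref}$; note that the published
gigantol-vs-model rate (−19.56%) is not reproducible from the published
group means (it recomputes to −16.36%) and the package reports only the
recomputed value.

# The synthetic-data world

The generators state a fixed world; their defaults are the published group
values and are never tuned against test outcomes.

* **Topography**: a spherical cap (apex height = cell height; footprint
  radius 12 µm) on a flat substrate, on a 30 µm field at 128 px, plus a
  correlated Gaussian texture (correlation length 2 px). The cap is the
  simplest shape with a well-defined apex height. The overview scan carries
  a small 20 nm instrument-level texture: at 234 nm/px it undersamples
  membrane texture anyway, and the profile maximum would otherwise be
  biased upward by extreme-value excursions of a 150 nm texture.
* **Local membrane patch**: a separate 5 µm / 64 px flat scan whose texture
  SD equals the cell's latent Rq — mirroring the real protocol of a local
  high-resolution scan for roughness. A Gaussian texture fixes
  $R_a/R_q = \sqrt{2/\pi} \approx 0.80$, so Ra and Rq cannot be pinned
  independently; the generator pins Rq, and the published orderings of both
  metrics are preserved (the published Ra/Rq pairs imply ratios 0.72–0.84,
  which a single stationary Gaussian texture cannot reproduce exactly).
* **Force curves**: the Hertz forward model with a hidden 100 nm piezo
  contact offset, 200 points over a 500 nm indentation ramp, additive
  Gaussian force noise (0.05 nN in cohorts), tip radius 20 nm and spring
  constant 0.4017 N/m (the imaging-probe configuration; the source lists a
  second, much stiffer probe — 6 nm, 45 N/m — and does not say which
  produced the stiffness figure, so both are constructible via
  `curve_spec()`).
* **Raman spectra**: sums of Lorentzian bands (FWHM 12 cm⁻¹, the standard
  Raman line shape) at the characteristic protein/lipid positions, a linear
  baseline, and 0.1% noise. Neighbouring Lorentzians overlap, so the
  generator solves the linear cross-talk system
  (`solve_band_amplitudes()`) to make the *composite* heights at the band
  centers — the quantity the analysis measures — equal their targets
  exactly; this is what "inverting the analysis equations" means for
  overlapping bands, and without it the 40 cm⁻¹ CH pair alone would be
  ~4% off in $S_l$.
* **Cohorts**: per-cell latent metric values drawn
  $\mathcal N(\mu_g, \sigma_g)$ per group (truncated to positivity), each
  realised as raw records via the generators above. Defaults
  (`default_cohort_spec()`): n = 20 cells/group and the published
  means/SDs — height 3.5/1.8/3.1 µm, Ra 112.25/144.2/114 nm, Rq
  155/176.6/135 nm, E 5.7/11.6/7.5 kPa, $S_l$ 0.7287/0.90807/0.75949,
  $S_t$ 0.41002/0.51303/0.42909 for control/model/gigantol.

**What a green test establishes — and what it does not.** Because the
published group values are generator presets, cohort recovery of those
numbers is a *self-consistency* check of the pipeline (generation →
serialisation → analysis → statistics), not an independent reproduction of
the biology. Features of real data the world does not model: cantilever
dynamics, thermal drift, tip convolution, adhesion, bottom-effect
stiffening of thin cells, cosmic-ray spikes, fluorescence backgrounds
beyond a polynomial, and any cell-shape complexity beyond a textured
spherical cap.

# Numerical choices and degenerate inputs

* Heights are stored in nm, reported heights in µm; moduli in kPa;
  roughness in nm — the printed-axis conventions.
* ROIs are 0-based half-open rectangles; a "5 µm" side is
  `round(5000/pixel_nm)` px.
* Profile interpolation is bilinear at ~1 px spacing; zero-length sections
  and sub-10-sample profiles are rejected.
* Contact-point search tolerance is $10^{-8}$ sample spacings; fits with
  fewer than 10 post-contact samples are errors, not silent results.
* Degenerate statistics follow fixed conventions: both groups constant and
  equal → p = 1; constant but different → p = 0; ANOVA on identical values
  → F = 0, p = 1.
* Readers reject ragged matrices, irregular or incomplete XYZ grids,
  duplicate wavenumbers, and missing probe metadata, naming the offending
  line; descending wavenumber order and unsorted indentation are repaired
  with a log line rather than rejected.
* At the ~1σ resolution limit of n = 20 cohorts, the unstarred
  gigantol-vs-control fluidity ordering is verified within sampling
  resolution (see the acceptance test comments) rather than as a strict
  inequality on one random draw.

# Known limitations

* Spherical Hertz only; no Sneddon cone/pyramid, no viscoelasticity, no
  adhesion (DMT offset fixed at 0), no bottom-effect correction.
* The stiff ALS default trades high-curvature background tracking for band
  fidelity; for strongly fluorescent backgrounds, lower `lam` and re-check
  heights on a known fixture.
* Peak heights are windowed maxima, not fitted amplitudes; at very low
  signal-to-noise a maximum is upward-biased. (Lorentzian fitting could be
  added behind `peak_height()` without touching the ratio layer.)
* JCAMP-DX support covers fixed-form `(X++(Y..Y))` tables — enough for
  spectrometer exports, not the full standard.

# Worked example

```{r example, eval = FALSE}
co <- gen_cohort(default_cohort_spec(n_cells = 20, seed = 7))
res <- analyze_cohort(co)
rep <- build_report(res)
rep$summary
rep$varrates
```

The same analysis runs from disk: `write_cohort()` then
`analyze_dataset("dir/manifest.tsv")`, or from a shell,
`Rscript -e 'lensmech::lensmech_cli()' simulate cohort --n-cells 20 --seed 7
--out-dir out` followed by `... analyze --manifest out/manifest.tsv
--out-dir out`.
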