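---
title: "Quantifying drought-induced carotenoid degradation from leaf Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drought-induced carotenoid degradation from leaf Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramandrought)
```

## The measurement and the statistic

Carotenoids scavenge the reactive oxygen species that accumulate in
chloroplasts under osmotic stress, and are consumed doing so. Their Raman
bands at 1007, 1157 and 1524 cm^-1 ride on a strong, smooth tissue
autofluorescence background, and their heights are proportional to carotenoid
concentration. Tracking the 1157 cm^-1 band height of living leaves over a
week of withheld water therefore yields a biochemical drought-stress readout
long before morphological symptoms appear. The 1524 cm^-1 band, although the
strongest carotenoid feature, overlaps the anthocyanin band present in young
seedlings, so quantification defaults to 1157 cm^-1 (`default_bands()`
computes all three and nominates 1157).

The phenotyping statistic is the relative degradation rate

\[
R \;=\; 100 \cdot \frac{A(\mathrm{day}~0) - A(\mathrm{day}~7)}{A(\mathrm{day}~0)} \quad (\%),
\]

where \(A\) is the preprocessed 1157 cm^-1 band amplitude. Larger \(R\) means
faster carotenoid loss, hence a more drought-sensitive genotype.

## Preprocessing chain

Each raw spectrum passes through three stages, in this order:

1. **Iterative polynomial baseline removal (modified polyfit).** A polynomial
   of order 7 (configurable 1-11; 5-9 is the conventional range for leaf
   autofluorescence) is least-squares fitted to the trace, every point above
   the fit is clamped down to it, and the fit is repeated until it changes by
   less than `tol_rel` x (intensity range) everywhere (default 1e-6), or
   `max_iter` (default 100) passes elapse. The limit is the lower envelope of
   the spectrum — the fluorescence background under the bands. Hitting the
   iteration cap is reported as a `converged = FALSE` flag, never an error:
   the envelope creeps slowly at the end and the residual drift is orders of
   magnitude below the band heights. The fitted baseline is not exactly
   pointwise monotone across iterations (a least-squares projection of a
   pointwise-smaller trace need not be pointwise smaller); the working trace
   is, by construction.
2. **Savitzky-Golay smoothing,** 15-point window, cubic polynomial, edges
   mirror-padded. A cubic at 15 points suppresses detector noise while leaving
   the ~16 cm^-1 wide carotenoid bands essentially undistorted; the filter
   reproduces any cubic exactly at interior points. A uniform wavenumber grid
   is required; non-uniform input is rejected with a resampling hint.
3. **Unit-vector normalization** over the full analysis grid (the
   conventional reading of the "unit vector method"): the trace is divided by
   its Euclidean norm, removing acquisition-to-acquisition intensity scale
   (laser power, focus). The full chain is therefore invariant to positive
   rescaling of the raw trace, verified to 1e-9 in the tests.

Normalization is applied per spectrum, *then* spectra are averaged
(per-spectrum normalization keeps acquisition-scale differences out of the
average); normalizing the mean spectrum instead would weight acquisitions by
their brightness. This is a genuine free choice and the package fixes it this
way throughout.

**Imaging mode differs deliberately:** `band_intensity_map()` applies baseline
removal and smoothing but *not* unit-vector normalization, because the Raman
images track absolute intensity loss across pixels and timepoints —
normalizing each pixel would cancel exactly the degradation signal the maps
exist to show. Per-pixel baseline correction is on by default
(`baseline = TRUE`); raw peak heights are available as a switch.

## The degradation-rate estimator

`fit_rates()` climbs the aggregation ladder of the in vivo design: mean of the
12 spectra per plant per day, mean over the 5 plants of a replicate,
two-point rate per replicate, then mean and standard error over the 3
replicate experiments. The SE is over replicates (n = 3), not plants, because
replicates are the independent experimental units. Group comparison uses
classical one-way ANOVA at alpha = 0.05 (`one_way_anova()`), with a Bartlett
test available as a variance-homogeneity diagnostic. Rates are interpreted
for stressed groups; control groups are reported alongside as drift checks.

For the mannitol map series, `time_to_fraction()` reports the first sampled
post-treatment timepoint at which the mean mapped amplitude falls to
`fraction` (default 0.5, a config value, not a constant of nature) of the
pre-treatment mean; `NA` means never.

## What the synthetic generator emulates

No instrument data ship with the package; `synth_spectrum()`,
`synth_study()` and `synth_map_series()` generate spectra with the
statistical structure the analysis assumes, so every stage is testable and
the printed study results can be reproduced by parameter recovery.

A leaf spectrum is composed of

* three carotenoid Lorentzians (1007/1157/1524 cm^-1, HWHM 7/8/9) whose
  common scale carries the degradation signal;
* a fixed set of leaf-matrix bands (chlorophyll, carbohydrate, CH-deformation
  regions, and an anthocyanin band at 1530 cm^-1 deliberately overlapping
  1524 cm^-1, which is why 1524 is excluded from quantification). Their
  summed spectral power is several-fold the carotenoid power, which keeps the
  unit-vector norm nearly constant as carotenoids decline — the regime the
  normalization step presumes;
* an autofluorescence background (cubic polynomial plus a broad Gaussian,
  sigma 300 cm^-1, i.e. deliberately *not* a polynomial, so the baseline
  stage is genuinely exercised);
* additive Gaussian detector noise (SD 1% of the tallest band) and
  per-spectrum multiplicative lognormal amplitude noise (CV 5%) — levels at
  which the 3 x 5 x 12 replication recovers rates to within ~1 point.

The default grid is 400-1800 cm^-1 at 1 cm^-1 (the bands of interest span
1007-1524 cm^-1; real spectrometer ranges vary and none is implied).

### Genotype profiles

`default_profiles()` encodes the study's six fixtures: inbreds CML176, OH28
and B73 with distinct initial 1157 amplitudes (1100/900/700 counts) and
7-day drought degradation fractions 0.22/0.20/0.06; near-isogenic lox2 and
lox4 sharing B73's initial amplitude (they are ~99.3% B73) with fractions
0.10 and 0.03; and dark-grown chlorophyll-less ("white") B73 tissue with much
lower carotenoid content, no chlorophyll bands and zero degradation under
osmotic stress (etioplast carotenoids are not consumed). Absolute amplitudes
are arbitrary detector counts chosen for realistic signal-to-noise; only
their ratios and the degradation fractions are meaningful.

### How the day-scale decay law is defined

The degradation fraction *r* is defined on the observable the pipeline
reports: the expected preprocessed (baseline-removed, smoothed,
unit-normalized) 1157 cm^-1 amplitude declines linearly from its day-0 value
to (1 - r) of it at day 7. Two subtleties make the raw Lorentzian amplitude
schedule nontrivial:

* unit-vector normalization couples the observable to the whole spectrum, so
  the map from raw carotenoid amplitude to normalized band height is smooth
  but not linear. The generator inverts this deterministic map numerically
  (root-finding against the actual preprocessing chain) when laying out the
  per-day amplitudes.
* additive detector noise distorts the *expected measured* amplitude by a
  small amplitude-dependent factor: noise power inflates the Euclidean norm,
  while the windowed maximum rides noise peaks. For noisy profiles the
  calibration targets the noise-expected observable, using a fixed-seed
  Monte Carlo estimate of this distortion spline-interpolated across
  amplitude anchors. The correction is conditioned on the profile's noise
  setting, so noiseless fixtures recover their rates exactly (to root-finder
  tolerance) and noisy ones are unbiased: over 20 seeds the estimator's mean
  error is a fraction of a point.

A linear (not exponential) day-scale law is used because the statistic is a
two-point relative change, which then recovers *r* exactly in expectation.

### Minute-scale mannitol kinetics

Leaf disks exposed to mannitol dehydrate in minutes; the generator models the
per-pixel expected 1157 amplitude as exponential decay towards a floor,

\[
A(t) = A_0\,\bigl[\,f + (1-f)\,2^{-t/\tau(c)}\,\bigr],
\]

with floor \(f = 0.1\) (a non-degradable residue keeps late-time maps from
going black, as observed) and degradable-pool half-lives
\(\tau = 9/5/3\) min for 100/150/250 mM. These half-lives were fixed, from
the closed form, so that the *mean mapped intensity* first drops below 50% of
pre-treatment at the 5-min sampled timepoint under 250 mM and at 15 min under
100 mM — the observed concentration-time pattern — with margin against the
generator's noise and the small constant-band pedestal under the 1157 window;
strict proportionality of rate to concentration would contradict that 5/15
pattern, so 150 mM sits between its neighbours rather than on a straight
line. Pixel-to-pixel carotenoid heterogeneity (lognormal, CV 12%) persists
across the timepoints of a series, as it would on a real leaf disk. Map
geometries follow the acquisition protocol: XY maps 180 x 140 um with 80
points, XZ depth maps 160 x 15 um with 30 points.

### What the generator does *not* emulate

Cosmic-ray spikes, wavenumber miscalibration, detector saturation, focus
drift within a map, plant-to-plant random effects beyond lognormal amplitude
scatter, chlorophyll fluorescence dynamics, and any physically calibrated
Raman cross-sections. Passing tests demonstrate that the pipeline recovers
the parameters of data with this structure; they cannot certify behaviour on
artefacts the generator omits.

## Numerical choices

* Baseline convergence: max |fit change| < 1e-6 x (raw intensity range);
  order-7 default. A degenerate all-zero spectrum converges immediately to a
  zero baseline.
* Band amplitude = windowed maximum over center +/- 10 cm^-1 (robust to a few
  cm^-1 of jitter; "peak height" is otherwise undefined on a discrete grid).
  Exact ties in `strongest_band()` break toward the lower wavenumber.
* Zero-norm spectra cannot be normalized and raise a validation error, as do
  empty groups, missing days, non-positive day-0 amplitudes and days not
  starting at 0.
* All simulation is seed-deterministic; generator-internal calibration uses
  its own fixed seed and never perturbs the caller's RNG stream.

## Problem sizes

The packaged tests and the acceptance script run the full in vivo design
(2 treatments x 3 replicates x 5 plants x 12 spectra x 8 days = 2880 spectra
per genotype; three genotypes per experiment) for the inbred and
near-isogenic recoveries, mannitol XY series of 6 x 80-spectrum maps per
concentration, and a 20-seed unbiasedness check on a reduced drought-only
design (3 x 4 x 6 x 8 spectra). The complete suite finishes in minutes on a
single CPU.

## Limitations

The estimator is a two-point contrast; it ignores the intermediate days
except for plotting and drift checks, and assumes day-0 amplitudes well above
noise. SE over three replicates is honest to the design but fragile to a
single aberrant replicate. The anthocyanin overlap is handled by exclusion
(1524 cm^-1), not by spectral unmixing. Real-data deviations from the
generator's assumptions — especially multiplicative plant effects and
non-smooth backgrounds — will widen the recovery error beyond what the tests
demonstrate.
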