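# ramandrought

Rank maize genotypes by drought tolerance from in vivo leaf Raman spectra.

Carotenoids are the chloroplast's first line of defense against the reactive
oxygen species that accumulate under osmotic stress, and they are consumed
doing so. Their Raman bands (1007, 1157, 1524 cm⁻¹) sit on a strong tissue
autofluorescence background, and their heights track carotenoid
concentration. Measuring the 1157 cm⁻¹ band of living seedling leaves across
a week of withheld water gives a fast, non-destructive drought-stress
phenotype: the faster a genotype's carotenoids degrade, the more drought
sensitive it is. The same signal, mapped across a leaf disk during mannitol
treatment, shows osmotic-stress kinetics on the scale of minutes.

The package implements the full analysis for both experiments:

- **Preprocessing** — iterative polynomial ("modified polyfit") baseline
  removal (order 7, clamp-and-refit to the lower envelope), Savitzky–Golay
  smoothing (15 points, cubic, mirror-padded), unit-vector normalization.
  The chain is invariant to acquisition intensity scale.
- **Quantification** — windowed peak heights of the carotenoid bands
  (`band_amplitude`, `strongest_band`, `mean_spectrum`). 1524 cm⁻¹ is the
  strongest carotenoid band but overlaps the anthocyanin band, so statistics
  default to 1157 cm⁻¹.
- **Rate estimation** — the relative degradation rate
  `R = 100 · (A(day 0) − A(day 7)) / A(day 0)` (%), aggregated
  spectra → plants → replicates, reported as mean ± SE over replicate
  experiments (`fit_rates`, an S3 model object with `print`, `summary`,
  `coef` and `plot` methods), with one-way ANOVA group comparison at
  α = 0.05.
- **Mapping** — per-pixel band-intensity images of XY (80-point) and XZ
  (30-point) map series (`band_intensity_map`, `render_map`), pooled
  histogram summaries (`map_summary`) and the time for the mean mapped
  intensity to fall to 50% of pre-treatment (`time_to_fraction`).
- **Synthetic data** — a generator (`synth_spectrum`, `synth_study`,
  `synth_map_series`, `default_profiles`, `default_kinetics`) that emulates
  the complete genotype × treatment × replicate × plant × day design and the
  mannitol map series, so the whole pipeline is testable and reproducible
  without instrument data.
- **Orchestration** — `run_pipeline()` drives simulate/load → preprocess →
  quantify → rates/maps → report from a single YAML config with a seed.

## Worked example

The packaged demo config simulates a reduced inbred study (3 replicates ×
3 plants × 6 spectra/day × 8 days for CML176, OH28 and B73) and runs the
full pipeline:

```r
library(ramandrought)
cfg <- system.file("extdata", "demo_config.yaml", package = "ramandrought")
res <- run_pipeline(cfg, out_dir = "demo_out")
print(res$fit)
#> Relative carotenoid degradation rates (day 0 to day 7), band carotenoid_1157
#>  genotype treatment n_rep rate_pct se_pct
#>    CML176   control     3   -0.752  0.878
#>      OH28   control     3   -0.766  0.436
#>       B73   control     3   -2.770  0.535
#>    CML176   drought     3   20.671  0.864
#>      OH28   drought     3   18.043  1.229
#>       B73   drought     3    6.020  0.995
print(res$summary$anova)
#> F(2, 6) = 56.37, p = 0.000129 *
```

Reading: under drought, CML176 loses ~21% of its 1157 cm⁻¹ carotenoid signal
in a week and B73 only ~6%, so B73 is the most drought-tolerant of the three
and CML176 the least; the well-watered controls only drift around zero (their
true change is 0; at this reduced design the drift spans a couple of points).
The ANOVA confirms the stressed-group rates differ across genotypes. The
output directory gains tidy CSVs (`amplitudes.csv`, `rates.csv`,
`replicate_rates.csv`, `anova.csv`), a trajectory figure and a `run_log.txt`
recording parameters, versions and the seed. At the full study design
(5 plants × 12 spectra) the recovered rates land within a fraction of a
point of the generator's 22/20/6%.

The minute-scale mannitol experiment:

```r
kin <- default_kinetics()
ser <- synth_map_series(kin, conc = 250, grid = "XY80", seed = 1)
time_to_fraction(ser, fraction = 0.5)
#> [1] 5
```

— under 250 mM mannitol the mapped carotenoid signal halves by the 5-minute
timepoint; with 100 mM the same loss takes 15 minutes (`conc = 100` returns
15), and the deionized-water control (`conc = 0`) never crosses (`NA`).

## Documentation

See the methods vignette (`vignettes/carotenoid-degradation.Rmd`) for the
model, the preprocessing and estimator choices, what the synthetic generator
does and does not emulate, and known limitations.
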