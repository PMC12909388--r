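# physgrowth

Growth-plate (physis) kinetics from pulsed fluorochrome double labeling.

Vertebral body tethering corrects spinal deformity by asymmetrically
modulating growth across the vertebral endplate (the Hueter–Volkmann
principle). Whether it works — and where in a multi-level construct it works
— is hard to see in macroscale Cobb angles. Fluorochrome double labeling
makes it directly measurable: a first label (alizarin red) given ~2 weeks
before harvest and a second (oxytetracycline) at harvest leave two datable
fluorescent fronts in the mineralising physis, and the distance between
them, divided by the elapsed days, is the local growth rate in µm/day.

`physgrowth` is the analysis side of that experiment, for researchers doing
growth-modulation work in large-animal models:

* **Front geometry** — physis-local frames, operator-traced label fronts as
  piecewise-linear polylines, pixel-by-pixel growth-distance fields measured
  along the axis of longitudinal growth.
* **Growth kinetics** — per-station rates, regional means over the anterior
  ¼ / middle ½ / posterior ¼ of the endplate, and the primary outcome

  ```
  %GM = 100 · (anterior ¼ rate − posterior ¼ rate) / overall mean rate
  ```

  (positive = anterior outgrows posterior, i.e. kyphosis-correcting), plus
  disk-level combination of the two physes flanking each disk space.
* **Morphometry** — zone thickness (area over A-P footprint), epiphyseal
  ossification fraction, nucleus pulposus centroid position, signed
  sagittal Cobb angles from endplate landmark lines.
* **Cohort statistics** — per-level aggregation, Grubbs' outlier test,
  one-tailed pairwise Welch t tests with Bonferroni correction, one-way
  ANOVA, post hoc power and required sample size from the noncentral t
  distribution, and reconstruction of leave-one-out sensitivity tables from
  printed means.
* **Synthetic data** — a two-channel label-band image generator with an
  exactly known growth field, and a multi-animal cohort generator with a
  prescribed level-wise modulation structure, so the whole pipeline is
  testable without any undeposited micrographs.

Inputs are two-channel TIFF micrographs with operator annotations in a
documented JSON schema (front control points, zone polygons, intervals,
endplate lines) plus a mandatory calibration (µm/pixel and days between
labels); outputs are long-format CSV cohort tables. `run_pipeline()`
orchestrates configuration-driven runs (`measure`, `morpho`, `stats`,
`simulate`) from a YAML config.

## Worked example

Simulate a labelled physis with a known 37.5% modulated growth field,
trace it with a simulated operator, and measure it back:

```r
library(physgrowth)

sim <- simulate_physis_image(image_sim_params(seed = 42, modulation_pct = 37.5))
m <- measure_physis(sim$annotation)
m$regional
#> <regional_rates> ant 1/4 194.87 | mid 1/2 164.02 | post 1/4 133.24 | overall 164.03 um/day
m$pct_growth_modulation
#> 37.57  (ground truth: 37.5)
```

The anterior quarter of this physis grows ~195 µm/day against ~133 µm/day
posteriorly — a 37.6% growth modulation relative to the 164 µm/day overall
rate, recovering the simulated truth to within a tenth of a point.

A six-animal cohort with the default effect structure (strongest modulation
at the most proximal instrumented disk D5, sign reversal at the adjacent
uninstrumented levels Dd/P1/P2 — the signature of junctional kyphosis):

```r
coh <- simulate_cohort(cohort_sim_params(seed = 1))
aggregate_levels(coh, group_by = "level")
#>   level   mean    sd n
#> 1    D1  10.88  7.94 6
#> 2    D2  12.83 15.74 6
#> 3    D3  19.09 24.43 6
#> 4    D4  33.77  9.87 6
#> 5    D5  48.94 11.22 6
#> 6    Dd  -8.65 11.77 6
#> 7    P1 -25.26 17.29 6
#> 8    P2 -17.75 11.67 6

grubbs_test(coh$pct_growth_modulation[coh$level == "D5"])
#> Grubbs' test (two_sided): G = 1.752, G crit(n = 6, alpha = 0.05) = 1.887 -> not an outlier

required_sample_size(d = 0.18, alpha = 0.05, power = 0.80)
#> 486
```

The last line is the sobering power arithmetic of small-effect levels: to
resolve a d = 0.18 difference between two adjacent disk levels at 80%
power, each group would need 486 animals.

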