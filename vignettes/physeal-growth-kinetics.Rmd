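---
title: "Measuring physeal growth kinetics from pulsed fluorochrome labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring physeal growth kinetics from pulsed fluorochrome labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physgrowth)
```

## The measurement problem

Systemic fluorochromes (alizarin red, oxytetracycline) bind to bone mineral
at the moment of administration, leaving datable fluorescent lines at
whatever surface was mineralising at that time. Giving one label 12--14 days
before harvest and a second at harvest brackets a known growth period: the
distance between the two label fronts, divided by the elapsed days, is the
local bone apposition (growth) rate. Applied to the two physes (growth
plates) of each vertebra in a tethered spine, this turns a micrograph into a
spatially resolved map of how a compressive implant redistributes growth
across the endplate — far more sensitive than macroscale Cobb angles.

`physgrowth` implements that measurement chain: operator-traced label
fronts, a pixel-wise growth-distance field measured along the axis of
longitudinal growth, regional growth rates, the percent growth modulation
statistic, physeal and epiphyseal morphometry, and the small-cohort
statistics used around them (Grubbs outlier screening, one-tailed pairwise
t tests under Bonferroni correction, one-way ANOVA, power analysis).

## Fronts, frames, and the distance field

Everything happens in a **physis-local frame**: an anterior--posterior (A-P)
unit vector along a user-chosen chord (anterior positive) and a growth unit
vector perpendicular to it. Pixel coordinates are 0-based, x rightward, y
downward; physical units enter only through a `calibration(um_per_px,
delta_days)` object, which is mandatory input — the scale of an
epifluorescence scan is never guessed from the image.

A traced front is the piecewise-linear interpolant of the operator's control
points, sorted by station; no smoothing is applied, and a front must be
single-valued in the A-P station. The growth-distance field is

$$d(x) = h_{\mathrm{new}}(x) - h_{\mathrm{old}}(x),$$

sampled at matched stations (default spacing 1 px) over the *intersection*
of the two traced extents; nothing is extrapolated. Distance is measured
along the frame's growth axis rather than along local front normals: this
realises "distance along the axis of longitudinal growth", keeps the field
single-valued under curvature, and makes the per-station rate simply
$r(x) = d(x)\cdot \mathrm{um\_per\_px} / \Delta t$.

Design choices worth stating:

* **Piecewise-linear fronts.** The original tracing workflow connects
  clicked points; whether it smoothed them is unknowable from the published
  description, so the package does not smooth. Interpolation at every
  control point is exact by construction (tested).
* **Signed distances.** Front crossings (new label behind old) are kept
  signed and surface in QC rather than being clamped away; a negative mean
  separation triggers a "fronts may be swapped" warning.
* **Chord-based regions.** The anterior quarter / middle half / posterior
  quarter split is taken on the normalised chord coordinate (the vertebral
  extent), not on arc length, mirroring the anatomical rationale: the
  annulus attaches at the anterior and posterior quarters, the nucleus
  pulposus occupies the middle half.

## Regional rates and percent growth modulation

With $s \in [0,1]$ the normalised station (1 = anterior), region means use
the bins $[0, 0.25]$, $(0.25, 0.75]$, $(0.75, 1]$. For uniformly spaced
stations whose count is divisible by 4 the weight identity

$$\bar r = 0.25\,\bar r_{\mathrm{ant}} + 0.5\,\bar r_{\mathrm{mid}} + 0.25\,\bar r_{\mathrm{post}}$$

holds to machine precision and is enforced by a property test. The primary
outcome is

$$\%GM = 100 \cdot \frac{\bar r_{\mathrm{ant}\,1/4} - \bar r_{\mathrm{post}\,1/4}}{\bar r_{\mathrm{overall}}},$$

positive when the anterior column outgrows the posterior
(kyphosis-correcting in a kyphotic model), negative when growth is actively
wedging the vertebra further into kyphosis. Because both numerator and
denominator are linear in the calibration, %GM is dimensionless: invariant
to `um_per_px` and `delta_days` (tested over random calibrations) and
antisymmetric under A-P reflection.

A disk space is flanked by two physes (the distal physis of the proximal
vertebra, the proximal physis of the distal vertebra). `combine_disk()` sums
their regional rates; the disk %GM is computed from the summed rates. Using
the summed overall rate as the denominator is identical to using the mean of
the two physes' overall rates (the factor of 2 cancels), so the choice is
cosmetic.

## Morphometry

* **Zone thickness** of a drawn polygon is area divided by its A-P footprint
  (the extent of its projection on the A-P axis) — the mean height of the
  region over its footprint. This is exact for any region bounded by two
  single-valued curves over a common footprint, reproducible, and stable on
  thin polygons where medial-axis definitions are not. The reported total
  physeal thickness is hypertrophic + proliferative/reserve.
* **Epiphyseal ossification** is the A-P length of the ossified epiphysis
  over the total epiphysis length, times 100; disk-level values average the
  two epiphyses facing the disk.
* **Nucleus pulposus position** is the area centroid of its polygon (the
  most standard reading of "geometric centre"; a bounding-box centre is not
  used), projected on the A-P axis and expressed posterior→anterior as a
  percentage of the ossified-epiphysis and whole-vertebra extents. Values
  outside [0, 100] are flagged, never clamped.
* **Cobb angle** between two endplate lines: magnitude is the acute angle
  between the directions (≤ 90°); the sign is kyphotic-positive, decided by
  comparing the inter-line gap at the anterior vs posterior ends of the
  shorter line's extent — robust for segments that do not intersect within
  the image.

## Cohort statistics

Sample (n−1) standard deviations are used throughout. Grubbs' test uses
$G = \max_i |x_i - \bar x| / s$ against

$$G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{n-2+t^2_{\alpha/(2n),\,n-2}}},$$

two-sided by default (one-sided by flag, with $\alpha/n$). The critical
values reproduce the published two-sided table for $n = 3\ldots10$ at
$\alpha = 0.05$ within 0.001. A six-animal cohort at $\alpha = 0.05$ has
$G_{crit} = 1.887$; published reports of $G_{crit} = 1.93$ at this $n$ and
$\alpha$ match neither the two-sided nor the one-sided convention, and the
package deliberately follows the standard formula.

Pairwise level comparisons use Welch's unequal-variance t test by default
(pooled-variance by flag; small cohorts give no basis to assume equal
variances) with one-tailed p values taken in the direction of the observed
difference, flagged at the Bonferroni-adjusted level $\alpha/\kappa$.
$\kappa$ is a caller input: the comparison family is an analysis decision,
not something to infer from the table shape.

Power calculations use the exact noncentral t distribution
($\mathrm{df} = 2n-2$, $\mathrm{ncp} = d\sqrt{n/2}$);
`required_sample_size()` starts from the normal approximation
$2(z_{1-\alpha/2}+z_{1-\beta})^2/d^2$ and iterates to the smallest integer n
meeting the target, cross-checked in tests against `power.t.test`. At
$d = 0.18$, $\alpha = 0.05$ two-sided and 80% power this gives 486 per
group (the normal approximation gives 484.6; published roundings as low as
480 are consistent with rounding of d).

`infer_excluded_value()` inverts leave-one-out means
($x = n\bar x_{all} - (n-1)\bar x_{-1}$), which lets a reader reconstruct
sensitivity analyses from printed descriptive statistics alone.

## The synthetic-data generators

No micrographs are publicly deposited for this kind of study, so the package
ships two generators that stand in for them, as first-class tested code.

**`simulate_physis_image()`** renders two Gaussian-profile label bands over
a shared smooth sinusoidal baseline into separate channels, with additive
intensity noise. The true separation field is *linear in the normalised
station*, $d(s) = A + Bs$ with $A,B$ chosen so the analytic %GM of the field
equals `modulation_pct` and its mean equals `base_separation_um` — so the
ground truth regional rates are closed-form, and curvature cancels from the
separation. Operator tracing is simulated by sampling `n_trace_points`
control points from the true fronts with Gaussian click jitter, and the
result carries a ready-made annotation set, so recovery tests exercise the
*identical* code path as real annotations. Defaults: 800×1024 px at 4
µm/px, 13 days between labels (the midpoint of the 12--14-day protocol
window — fixtures only; real analyses must pass the true per-animal
interval), 2132 µm mean separation (an overall rate of 164 µm/day), band
σ = 4 px, noise 5% of peak, 40 trace points with 0.5 px jitter. What the
generator does **not** emulate: band-width asymmetry, label diffusion,
tissue autofluorescence, tearing/folding artefacts, and operator bias that
correlates along the front — so recovery tests bound geometric and
sampling error of the measurement chain, not segmentation difficulty on
real histology.

**`simulate_cohort()`** draws per-animal, per-level %GM as level effect +
shared animal offset + measurement noise, and constructs regional rates
that realise each draw exactly (anterior/posterior = overall ± δ with
δ = gm·overall/200). Default level effects follow the reported effect
structure: D5 = 55, D1--D4 = {7, 11, 16, 21}, adjacent levels (Dd, P1, P2)
= −20. The adjacent-level magnitude is declared arbitrary: only its sign is
anchored in evidence. Between-animal SD 8 and within-level SD 15 put the
strongest level near 55 ± 17. An optional `failure_injection` multiplies
one animal-level's modulation by an attenuation factor, emulating an
implant failure, and flags the row.

Both generators are pure functions of their parameters and seed
(bit-identical on repeat calls, tested).

## Numerical choices and degenerate inputs

* Region binning at exactly $s = 0.25, 0.75$ follows the half-open bins
  above; A-P flip antisymmetry is exact whenever no station lands on a bin
  boundary (station counts divisible by 4), which the tests use.
* Regional means at spacing 1 px differ from the continuum closed form by
  O(spacing/extent); recovery tolerances absorb this.
* Duplicate front stations within 1e-9 px, coincident chord endpoints,
  zero-variance Grubbs input, sub-4-spacing front overlap, polygons with
  self-intersections or zero A-P extent, and ossified intervals exceeding
  the total all raise immediate errors rather than propagating NaN.
* `required_sample_size()` returns the boundary minimum n = 2 when the
  target power does not exceed the test's size.

## Problem sizes in the test-suite and acceptance script

Image-recovery checks use the default 800×1024 px scene across 20 seeds
plus one noise-free scene; statistical calibration uses 5000 null
replicates for the Grubbs type-I rate (n = 6) and 2000 for the ANOVA
p-value uniformity KS check; cohort-structure checks use 50 seeds of the
default six-animal cohort. These sizes give Monte-Carlo standard errors
comfortably below the tolerances they are compared against.

## Known limitations

* Front tracing is operator-seeded; there is no automatic front detection
  from pixel intensities, and the synthetic operator is unbiased — real
  inter-operator variability must be assessed externally.
* "Average thickness" of a drawn area follows the area-over-footprint
  definition; proprietary implementations in commercial histomorphometry
  software may differ in unspecified ways.
* The cohort simulator models level effects and an animal random effect but
  not within-animal spatial correlation between adjacent levels.
* No DICOM/CT reconstruction: only the Cobb computation from landmark lines
  is in scope.
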