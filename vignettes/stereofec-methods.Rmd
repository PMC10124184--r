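---
title: "Stereological fecundity estimation for venerid clams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological fecundity estimation for venerid clams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Partial fecundity (PF) — the number of mature oocytes a ripe female can shed
in one spawning event — is a core quantity for the management of the striped
venus clam and similar multiple partial spawners. It cannot be observed
directly: it must be reconstructed stereologically from serial histological
sections of the gonad. The same histological material also supports two other
classical analyses: the logistic size-at-maturity ogive (TL50) and
descriptive phenology (monthly maturity-stage composition against bottom
temperature and chlorophyll-a).

`stereofec` implements that whole chain, and — because raw histological
material is rarely shareable — pairs it with a *synthetic gonad generator*
that produces three-dimensional organs with known ground truth. Every
estimator in the package can therefore be validated by recovery: generate an
organ with known oocyte counts and occupancy, observe it exactly the way a
histologist would, and check that the estimates come back unbiased.

## The observation model

A gonad is modelled as a prolate ellipsoid with a 2:1:1 axis ratio, scaled so
its volume follows the organ-size allometry

  G_v = 17.2 * TL - 304.5   (mm^3, TL in mm),

with multiplicative lognormal noise (mean 1) of coefficient of variation
`gv_noise_cv`. Oocytes are oblate spheroids with equatorial diameter d_max,
polar diameter d_min = aspect * d_max (aspect ~ Uniform(0.65, 0.95)) and a
concentric spherical nucleus of diameter 0.35 * d_max. They are placed
uniformly in the organ with isotropic orientations, overlap permitted — a
Boolean (germ-grain) model. The estimators observe *profiles*, not packing,
so ignoring exclusion keeps generation linear in oocyte number without
touching any tested contract.

Virtual histology mirrors the laboratory protocol: one 6-um section every
100 um perpendicular to the organ's major axis, the gonad cross-section area
G_a recorded per section, and six rectangular microscope fields (870 x 660
um, a 10x camera field; the true field size at 10x is not published, so this
default is declared, not inferred) placed uniformly at random wholly inside
the cross-sections, spread evenly over the sections large enough to hold
one. A slab reports, per intersected oocyte, the largest in-plane
cross-section over the planes it contains (a thin section approximates a
single plane); for a spheroid every central section exposes the full
equatorial diameter, so near-nuclear cuts read d_max almost exactly.

Two nucleus-counting rules are implemented. `"intersect"` counts a profile
when the slab geometrically cuts the nucleus — what an observer actually
sees when scoring "oocytes sectioned through the nucleus" — and requires the
Abercrombie correction T/(T + h) (T section thickness, h mean nucleus
diameter) to undo the (T + h)/T over-counting. `"center"` counts a profile
only when the slab contains the nucleus center; it is correction-free and
unbiased by construction, and serves as the internal oracle the intersect
rule is reconciled against in the tests.

## The estimators

* **Gonad volume**: Cavalieri sum, `sum(G_a) * spacing`. The integration
  method behind published G_v values is usually unstated; the Cavalieri
  estimator is the standard unbiased choice and is exact for constant
  cross-sections.
* **Counts**: class-wise nucleus-profile counts over the fields, divided by
  the sampled tissue volume (total field area x thickness), Abercrombie-
  corrected under the intersect rule, then scaled by the reconstructed
  volume. PF is the mature-oocyte total of a ripe (4A) female.
* **Oocyte volume**: `mode = "corrected"` (default) uses pi/6 * d_min *
  d_max^2, i.e. diameters as diameters. The formula printed in parts of the
  bivalve literature, 4/3 * pi * d_min * d_max^2, treats diameters as
  semi-axes and overestimates a sphere exactly 8-fold; it is retained as
  `mode = "paper"` for literal reproduction only. Whether radii or diameters
  were intended is unresolvable from the published text, so both modes ship
  and every estimate is labelled with the mode that produced it; generator
  and estimator always share one mode in recovery tests.
* **Occupancy**: estimated count x mean profile volume / gonad volume,
  per class. Under the intersect rule, nucleus-hit profiles oversample
  large oocytes (inclusion probability proportional to T + h), which at the
  default diameter spreads inflates a plain mean oocyte volume by roughly a
  quarter. The class mean is therefore an inclusion-probability-weighted
  (Horvitz-Thompson) mean with weights 1/(T + estimated nucleus diameter);
  the unweighted mean stays available (`size_bias_correction = FALSE`), as
  does a Delesse areal-fraction occupancy (`method = "delesse"`) as a
  sensitivity check (approximate in thick sections, since slab profiles are
  maxima rather than point-plane sections).

A small residual bias remains by design: profile minor axes of tilted
spheroids are slightly inflated relative to d_min (the section ellipse's
minor axis exceeds the polar diameter unless the cut is exactly equatorial),
which the near-central k-factor only partly offsets. Net effect on mean
oocyte volume is about +1–2%, well inside the sampling variation of a
30-gonad cohort; the tests quantify it rather than hide it.

## Maturity and cohort statistics

Females are mature when any oocyte exceeds d_max = 60 um (vitellogenesis
threshold); an empty smear classifies as immature, reading the "only
previtellogenic oocytes" rule vacuously. Males are mature iff elongated
spermatozoa are present. The ogive is a binomial GLM of the proportion
mature per 1-mm size class on the class midpoint, weighted by class size —
fitting on class proportions (not raw individuals) mirrors the field
protocol; the published exponent "a + bcx" is read as a typo for a + bx,
since exactly two constants are declared. TL50 = -a/b carries a delta-method
SE; a bootstrap interval is available behind a flag, as no published CI
method exists to match. Complete separation yields a flagged fit, not a
failure. Indeterminate individuals are excluded.

Cohort statistics are deliberately classical: OLS with mean-response
t-intervals (the published "95% CI" is not identified as mean vs individual;
the prediction-interval variant sits behind a flag), type-II sums of squares
for the unbalanced 20/6 two-way occupancy ANOVA, Tukey HSD on cell and
marginal means using the studentized range with harmonic-mean cell sizes,
and an ANCOVA of log counts on log length preceded by an explicit
homogeneity-of-slopes test. The published ANOVA table's exact F values and
Tukey differences depend on per-female raw data that are not public; the
package reproduces them as *sign and significance properties* on synthetic
cohorts instead. The MCRS scenario evaluates the PF regression at the new
(22 mm) and old (25 mm) reference sizes and reports the relative change in
both directions — "x% fewer eggs at 22 than 25" and "y% more at 25 than 22"
are different numbers (about 39% and 64% under the published coefficients),
and public summaries have used "40%" for both; the raw value is always
reported next to the rounded headline.

## Generator calibration choices

The generator's defaults are the study conditions:

* occupancy targets 19.1/20.5% (stage 4A mature/immature) and 7.8/14.0%
  (stage 4B); calibration adds oocytes until each class's geometric volume
  fraction is within one oocyte of its target;
* d_max class means 70.3/41.5 um (4A) and 70.1/38.6 um (4B) inside the
  stage-wide ranges [5.85, 154.89] and [9.54, 139.21] um. The configured
  means are *realized truncated means*: the normal location is solved by
  root finding so that the class-truncated distribution (mature on
  (60, hi], immature on [lo, 60], keeping the d_max > 60 um dichotomy
  exact) has precisely the configured mean. Spreads are free parameters
  (SD 25 um mature, 15 um immature) since only means and ranges are
  published;
* the count calibration mode instead draws the mature count from
  PF = 3.01e4 * TL - 5.21e5 and lets occupancy emerge; the two modes exist
  because the published occupancy fractions, diameter means and the two
  regressions are not jointly consistent with a single simple model;
* noise defaults `gv_noise_cv = 0.10` and `pf_noise_cv = 0.20` are chosen
  so simulated cohorts at the study design reproduce the published adjusted
  R^2 of 0.97 (G_v ~ TL, n = 26) and 0.85 (PF ~ TL, n = 16);
* ogive defaults a = -14, b = 1.25 mm^-1: TL50 = 11.2 mm with
  P(mature | 15 mm) = 0.991, matching "all mature above 15 mm";
* nucleus diameter fraction 0.35 (germinal vesicle about a third of the
  cell diameter) and the 2:1:1 organ shape are unpublished quantities set
  once to field-plausible values. Oogonia are not a separate class; they
  fall under immature. Published size-frequency modes ("53 mm"/"41 mm",
  clearly um) are not used for calibration.

## What the synthetic data do and do not show

The generator reproduces the *statistical* structure the estimators rely on
— occupancy fractions, diameter distributions, organ allometry, Bernoulli
maturity — not histology: no follicle architecture, no spatial clustering
of oocytes, no stain/contrast artefacts, no lost or folded sections, no
male gamete geometry (male maturity is Bernoulli-only). Passing recovery
tests therefore demonstrates that the estimation chain is internally
unbiased under the stated observation model; it cannot certify robustness
to segmentation error or non-uniform oocyte placement in real tissue.

## Numerical and reproducibility choices

All geometry is carried in micrometres internally, mm/mm^3 only at I/O.
Slabs are half-open intervals [z_start, z_start + thickness); sections are
indexed from zero along the organ's axial extent. Every stochastic step
takes an explicit seed, and pipeline stages derive their own seeds from the
master seed and the stage name, so identical configurations give
bit-identical outputs (the run manifest hashes depend only on config and
seed). Truncated normals are sampled by inverse CDF; the location solver
brackets adaptively before `uniroot`. Fields must fit wholly inside the
circular cross-section (centers drawn by rejection from the valid-center
box); a field larger than every cross-section is an error rather than a
clipped observation, because clipped fields would bias number densities.

Problem sizes: a natural-size ripe gonad at TL 25 mm holds roughly 1.5e5
mature and 7e5 immature oocytes, and recovery suites over such organs use
30 gonads per stage. Property-style simulations that only exercise
estimator *distributions* (e.g. the 200-seed Tukey sign property at the
20/6 design) run on organs scaled to one tenth of natural volume via
`volume_scale`: occupancy estimates depend on field-local densities, not
organ size, so the scaled runs preserve the tested property while keeping
the suites fast. The scale choice is stated in each test.

```{r example}
library(stereofec)
cfg <- generator_config(gv_noise_cv = 0)
g <- generate_gonad(25, "4A", cfg, seed = 1)
tab <- observe_gonad(g, section_plan(), seed = 2)  # section + sample fields
estimate_fecundity(tab, config = cfg)
```

## Known limitations

* The occupancy estimator's +1–2% mean-volume bias under the intersect rule
  (tilted-profile minor-axis inflation) is documented, not corrected; an
  exact correction would need the latent orientation of each profile.
* The Delesse flag uses slab-maximal profiles and therefore overstates areal
  fractions in thick sections; it is a sensitivity check, not an estimator.
* Published ANOVA F values are not reproducible without the raw per-female
  table; only their qualitative structure is testable.
* The phenology module is descriptive by design: the published link between
  temperature, chlorophyll-a and spawning is narrative, and fitting an
  environmental trigger model would be invention.
* Egg viability adjustments are out of scope; PF counts morphologically
  mature oocytes.
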