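---
title: "Modeling the ontogeny of a soaring bird's energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the ontogeny of a soaring bird's energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Obligate soaring birds such as golden eagles extract the energy for flight
from the atmosphere, chiefly from orographic uplift: air deflected upward
where wind meets ridges and rugged terrain. Which parts of a landscape are
cheap to traverse therefore depends on topography — but also on the bird.
Juveniles must learn to find and exploit uplift, so the portion of the
*fundamental* energy landscape that an individual can actually use (its
*realized* energy landscape) should expand with age.

`eaglescape` implements a complete analysis chain for quantifying this
expansion from GPS bio-logging data, together with a synthetic world in
which the entire chain can be verified against known ground truth:

1. **Terrain metrics** — the two uplift proxies: the topographic ruggedness
   index (TRI, mean absolute elevation difference to the adjacent cells)
   and the distance to ridge lines. Ridges are the cells whose standardized
   topographic position index (TPI, focal elevation minus the mean over an
   annulus of 10–200 m) exceeds +1 SD, the "ridge" class of the standard
   TPI landform convention; distance is an exact Euclidean distance
   transform. Both layers are block-averaged to a 100 m analysis grid.
2. **Track segmentation** — flight altitude above ground (ellipsoid height
   minus geoid undulation minus DEM), position-based ground speed, and a
   population-level two-class EM of each variable; the high-speed,
   high-altitude (HH) corner marks commuting flight. Commuting bouts are
   runs of at least two consecutive hourly HH fixes (≥ 1 h nonstop).
3. **Dispersal detection** — an individual is dispersed after more than 14
   consecutive days without any fix inside a 7 km radius of its nest
   (30 km for individuals with unusually large natal territories); weeks
   since emigration count from the last inside fix before that absence.
4. **Step-selection sampling** — each pair of consecutive hourly commuting
   fixes is an observed step; 50 alternative steps per observed step are
   drawn from a gamma step-length kernel and a von Mises turning-angle
   kernel fitted to the observed steps, sharing the start point. All end
   points carry TRI and distance-to-ridge from the 100 m layers; all
   predictors (TRI, distance to ridge, step length, week since emigration)
   are z-transformed, and pairwise correlations are screened at |r| ≥ 0.5.
5. **The step-selection model** — a conditional logistic regression over
   matched strata (1 used + 50 available), with main effects of the four
   predictors and the two- and three-way products of each terrain variable
   with step length and week, plus step length × week. The likelihood,
   analytic gradient and Hessian are implemented directly with log-sum-exp
   stabilization and Newton iterations; standard errors come from the
   inverse observed information. Individual variation enters as Gaussian
   random slopes on TRI and distance to ridge via the Poisson
   reformulation of the conditional logit (stratum intercepts as random
   effects with variance fixed at 10^6), fitted with glmmTMB.
6. **Energy landscapes** — the inverse logit of the fixed-effects linear
   predictor, evaluated per 100 m cell for each week since emigration with
   that week's mean observed step length, is the *flyability* index in
   [0, 1]. Cells above 0.7 are flyable; their count × 0.01 km² is the
   weekly flyable area, whose trajectory is fitted with a logistic growth
   curve; hotspots are a Gaussian KDE of flyable-cell centres.

## The synthetic world

The generator produces a planar, metric world: ridge crests with Gaussian
cross-sections plus smooth low-frequency noise, at 50 m resolution over
160 × 160 km by default. Agents live on this terrain with a known movement
model:

* Hourly commuting decisions follow a step-selection rule: candidate end
  points are drawn from the generating kernels (gamma length, von Mises
  turn; uniform bearing at bout starts) and one is chosen with probability
  proportional to `exp(beta . z)`, where `z` holds the z-scored TRI,
  distance to ridge and step length of the candidate and their products
  with the z-scored week. Candidates falling outside the raster are
  redrawn, so availability is the extent-truncated kernel — exactly what
  the analysis-side sampler uses.
* The default coefficients encode the study's qualitative pattern:
  preference for rugged terrain near ridges and for long steps, terrain
  preferences attenuating with week and the step-length preference
  strengthening (`tri` +0.8, `dist_ridge` −0.8, `step_length` +0.5,
  `tri_week` −0.4, `dist_week` +0.4, `step_week` +0.35, and ±0.15 on the
  step-length products). The week main effect is constant within a stratum
  and therefore carries no selection and no estimate.
* Behaviour alternates between commuting bouts (geometric, mean 3 h) and
  non-commuting gaps (geometric, mean 250 h), giving about two commuting
  steps per week — with 20 individuals over 100 weeks, roughly 4,000
  strata per run. Commuting fixes carry the high speed/altitude class
  (speed ~ N(12, 2) m/s, altitude ~ N(300, 80) m), other fixes the low
  class (N(1, 0.5) m/s, N(20, 15) m). At one fix per 20 min, a 12 m/s
  commuting hour implies hourly steps of 43.2 ± 7.2 km, i.e. a gamma
  kernel with shape 36 and scale 1,200 m: the two halves of the generator
  are kept mutually consistent.
* `height_ellipsoid` = geoid offset + DEM elevation at the fix +
  behaviour-dependent flight altitude + N(0, 10 m) GPS noise.

### What recovery does and does not show

Two deliberate choices make parameter recovery a sharp test:

* **Candidate count.** Selecting among M kernel draws approximates the
  continuous density `kernel × exp(beta . z)` only up to a resampling
  error of order 1/M. The default M is set large enough (see
  `sim_config()`) that this error is far below the precision of a
  4,000-stratum fit, while remaining unrelated to the analysis' 50
  alternatives.
* **Known availability and scale.** Recovery experiments pass the
  *generating* kernels and the world-level z-transform constants (recorded
  in the config at generation time) to the sampler and the fit, because
  the generating coefficients are defined on that scale and against that
  availability. The data-driven pipeline instead refits kernels to the
  observed (selection-tilted) steps and z-transforms from the dataset, as
  one must on real data; this reparameterizes the step-length terms (the
  familiar availability issue of integrated step-selection analyses), so
  numeric equality with the generating coefficients is only meaningful in
  the known-availability design.

The synthetic world emulates sampling cadence, behavioural structure,
altitude noise, and selection; it does **not** emulate weather, thermal
uplift, GPS fix loss, territorial interactions, or memory. Passing tests
shows the *estimation machinery* is correct and calibrated, not that real
eagle data meet the model's assumptions.

## Numerical choices

* Conditional logit: Newton with step halving; convergence at gradient
  sup-norm < 1e-6 (max 500 iterations); log-sum-exp stabilization of every
  stratum sum; coefficients beyond ‖β‖∞ = 50 on the z-scale raise a
  separation error naming the covariate. Columns constant within every
  stratum are dropped (reported NA), mirroring how matched conditioning
  absorbs them.
* EM segmentation: two-component 1-D EM per variable, means initialized at
  the 25th/75th percentiles, SDs at the pooled SD; convergence at
  log-likelihood change < 1e-8 (max 500 iterations); a collapsed component
  (SD < 1e-6) triggers up to 5 perturbed restarts; mixture means closer
  than 2 SD log a low-separation warning. A posterior of exactly 0.5 goes
  to the low class.
* Hourly subsampling keeps the fix nearest each whole hour within ±10 min;
  bout runs break at gaps > 75 min.
* von Mises MLE: closed-form mean direction; concentration solves
  A1(κ) = R̄ by bisection, capped at κ = 500 with a warning for degenerate
  angle sets. Gamma MLE via `fitdistrplus` with moment starts.
* TPI annulus is strict-inner/inclusive-outer in centre-to-centre
  distance, so at 25 m cells the default 10 m inner radius excludes only
  the focal cell. Distances are exact Euclidean (Felzenszwalb–Huttenlocher
  transform), not chamfer approximations.
* Logistic growth by Levenberg–Marquardt least squares with positivity
  constraints; a failed fit or a near-zero rate is flagged, never thrown;
  fold change is undefined (flagged) when the first week's area is 0.
* Hotspot KDE: separable Gaussian convolution truncated at 6 SD,
  bandwidths from Silverman's rule per axis, renormalized to integrate to
  1 over the region.

## Design choices where the design was open

* **Week main effect.** Week is shared by all members of a stratum, so its
  main effect is unidentifiable under matched conditioning; it is kept in
  the design for completeness and reported NA rather than silently
  omitted.
* **Step length × week.** The three-way products imply this two-way
  margin, and the ontogenetic strengthening of the step-length preference
  is part of the phenomenon being modelled, so the design includes it
  (making the model hierarchical).
* **Emigration anchor.** The recursion rule defines *that* a bird
  dispersed; the emigration instant is anchored at the last fix inside the
  radius before the qualifying absence — reproducible and conservative.
  Any single fix inside the radius counts as a recursion.
* **One fixed world per recovery experiment.** Replicate seeds redraw
  tracks and sampling, not terrain, mirroring a study design with one
  landscape and many individuals; terrain variation across replicates
  would only add between-world variance without testing anything extra.
* **Problem sizes.** The study-scale experiments use 20 individuals × 100
  weeks (≈ 4,000 strata) for recovery and a 6-individual × 156-week cohort
  for the weekly landscape series; full-resolution 20-min track emission
  is exercised on smaller cohorts (2–4 birds, 2–6 weeks), which is ample
  to validate segmentation at the fix level.

## Known limitations

* The EM segmentation is two independent 1-D mixtures, not a bivariate
  clustering with delimiters; only the HH corner is consumed downstream,
  which this preserves, but the other three corners should not be
  over-interpreted.
* Real-data mode expects projected (metric) coordinates; no CRS handling
  or reprojection is included, and raster I/O is plain-text ASCII grid.
* Flyability is a relative preference index on [0, 1], not an energetic
  quantity in joules; comparisons are meaningful across weeks within one
  fitted model, not across models.
* Predictions at weeks far beyond the observed range extrapolate the
  week interactions linearly on the z-scale and should not be trusted;
  the landscape series therefore uses simulated cohorts spanning the full
  156 weeks when the 3-year axis is needed.
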