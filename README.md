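# eaglescape

Tools for quantifying how the *realized energy landscape* of a soaring
raptor develops with age, and a synthetic world in which every stage of
that analysis is verifiable against known ground truth.

## The problem

Soaring birds such as juvenile golden eagles power their flight with
orographic uplift — air deflected upward by rugged terrain and ridge
lines. Where a bird can fly cheaply therefore depends on topography, but
also on the bird: juveniles must learn to find and exploit uplift, so the
usable ("realized") portion of the landscape's energy should expand along
the ontogenetic axis. `eaglescape` implements the full analysis chain for
testing this with GPS bio-logging data:

* **Terrain uplift proxies** — topographic ruggedness index (TRI; mean
  |Δelevation| to the adjacent cells) and distance to ridge lines (ridges
  = standardized topographic position index > +1 SD, with an exact
  Euclidean distance transform), block-averaged to a 100 m grid.
* **Track segmentation** — flight altitude above ground (ellipsoid −
  geoid − DEM), position-based ground speed, two-class EM per variable at
  the population level; the high-speed/high-altitude corner is commuting
  flight, and commuting bouts are ≥ 1 h of consecutive hourly HH fixes.
* **Dispersal detection** — emigration is > 14 consecutive days without a
  recursion into a 7 km nest radius; weeks since emigration count from
  the last fix inside.
* **Step-selection function (SSF)** — each observed hourly commuting step
  is matched with 50 alternatives drawn from fitted gamma (step length)
  and von Mises (turning angle) kernels; a conditional logistic model
  over the matched strata estimates selection,

  `P(step | stratum s) = exp(βᵀx) / Σ_{j∈s} exp(βᵀx_j)` ,

  with z-scored TRI, distance to ridge, step length and week main effects
  and the two- and three-way interactions of the terrain variables with
  step length and week (plus step length × week). Individual random
  slopes on the terrain variables use the Poisson reformulation (glmmTMB).
* **Energy landscapes** — *flyability* = inverse logit of the fixed-effects
  linear predictor per 100 m cell and week; cells above 0.7 are flyable;
  the weekly flyable-area series gets a logistic growth fit, a fold
  change, and Gaussian-KDE hotspot maps.

The synthetic world (`sim_config()`, `build_world()`, `simulate_track()`)
generates ridged terrain and agents whose hourly step decisions follow a
*known* selection rule, so parameter recovery closes the loop on the whole
pipeline.

## Worked example

```r
library(eaglescape)

world <- build_world(sim_config(seed = 42, n_individuals = 6,
                                extent_m = 40000, cell_m = 100,
                                gamma_shape = 36, gamma_scale = 150,
                                post_emigration_weeks = 10,
                                commute_gap_mean_hr = 30))
rec <- recovery_replicate(world, seed = 42)   # simulate, sample, fit
print(rec$fit)
```

```
ssf_fit (newton): 941 strata, logLik -2665.68
               estimate     se ci_lower ci_upper
tri              0.7874 0.0497   0.6900   0.8849
dist_ridge      -0.8139 0.1164  -1.0420  -0.5857
step_length      0.6024 0.0713   0.4627   0.7421
week                 NA     NA       NA       NA
tri_step         0.1298 0.0370   0.0573   0.2023
dist_step       -0.1531 0.0920  -0.3334   0.0272
tri_week        -0.4335 0.0563  -0.5438  -0.3233
dist_week        0.4311 0.1201   0.1957   0.6664
step_week        0.2596 0.0657   0.1308   0.3883
tri_step_week   -0.0539 0.0387  -0.1297   0.0219
dist_step_week   0.1591 0.0846  -0.0067   0.3249
dropped (stratum-constant): week
```

The generating coefficients were `tri` +0.8, `dist_ridge` −0.8,
`step_length` +0.5, `tri_week` −0.4, …: the estimates land near the
truth with the generating signs, and `week` is reported NA because a
covariate shared by a whole matched stratum carries no information under
stratum conditioning. From such a fit,

```r
series <- landscape_series(rec$fit, world$terrain, rec$steps,
                           weeks = 1:10, params = rec$params)
print(series)
```

```
landscape_series: 10 weeks, threshold 0.70
  flyable area: 790.31 km2 (week 1) -> 978.87 km2 (week 10)
  fold change: 1.239
```

The weekly flyable area (km² of 100 m cells with flyability > 0.7) grows
across weeks as the fitted week interactions attenuate the terrain
dependence — the landscape "opens up" as the agent ages.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow at study scale (01 world, 02 full-track simulation and
segmentation, 03 stratified sampling and SSF fit, 04 parameter recovery
across 20 replicate datasets, 05 the 156-week energy-landscape series),
writing their tables under `results/`.

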