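# fptforage

Foraging-behaviour analysis for high-frequency GPS tracks of central-place
foraging seabirds, with habitat-preference estimation against daily
satellite-sensed oceanographic fields.

Tropical pelagic seabirds such as tropicbirds make looping trips from their
colony over an ocean whose productivity cues (temperature, turbidity,
chlorophyll) shift almost completely from one day to the next. `fptforage`
is for movement ecologists who want to ask, from 1-fix-per-minute GPS
tracks and daily gridded covariates, *where these birds choose to search
for food*:

1. **First-Passage Time (FPT) segmentation.** For each track location and
   circle radius $r$, FPT is the time to cross the circle (backward +
   forward passage). The radius at which $\mathrm{var}\,\log
   \mathrm{FPT}(r)$ peaks is the scale of Area-Restricted Search (ARS);
   the median of per-trip peaks is the working scale. At that scale, fixes
   with FPT above a threshold (default 300 s) are `search`; the lower half
   of the remaining low-FPT band is `travel`; intermediate fixes are
   excluded. Fixes slower than 10 km/h (the bird sitting on the water) are
   removed first.
2. **Covariate annotation.** Daily rasters of SST (°C), turbidity
   (Kd(490), m⁻¹) and chlorophyll-a (mg m⁻³) are aggregated to 0.05°,
   averaged with the previous day's image, rank-standardised within the
   study window onto a 0–20 scale, and sampled at each fix by its own UTC
   date.
3. **Binomial random-intercept GLMM.**
   $\mathrm{logit}\,P(\mathrm{search}) = \beta_0 + \beta^\top x + \alpha_i$,
   $\alpha_i \sim N(0,\sigma_\alpha^2)$ per bird, fitted by adaptive
   Gauss–Hermite maximum likelihood (25 nodes), with Wald tests and
   marginal/conditional (variance-partition) $R^2$ using the logit-link
   distribution-specific variance $\pi^2/3$.

A seeded simulator (`sim_config()`, `simulate_tracks()`) generates fleets
of two-mode correlated-random-walk trips over synthetic ocean fields with
known ground truth for every stage, so the whole pipeline is testable
without field data. See the methods vignette
(`vignettes/foraging-habitat-analysis.Rmd`) for the model details and
design rationale.

## Worked example

```r
library(fptforage)
library(dplyr)

cfg <- sim_config(n_individuals = 5, trips_min = 1, trips_max = 2, seed = 42)
sim <- simulate_tracks(cfg)

report <- run_pipeline(pipeline_config(
  tracks  = select(sim$fixes, individual_id:lat),
  rasters = sim$rasters,
  window  = cfg$window))
report
```

```
<pipeline_report>
ARS scale: 665.3 m
       stage    n
         raw 3132
 regularised 3132
 non_sitting 2781
 fpt_defined 2597
  classified 1585
    modelled 1585

Binomial random-intercept GLMM (adaptive Gauss-Hermite, 25 nodes)
1585 observations, 5 groups; logLik -1001.73

               Estimate    SE     Z P-value
(Intercept)      -1.004 0.236 -4.26  <0.001
sst_rank          0.072 0.012  6.02  <0.001
turbidity_rank   -0.018 0.012 -1.51    0.13
chla_rank        -0.005 0.012 -0.40    0.69

Random intercept variance: 0.04762
R2 cond./marg.: 0.06/0.04
```

Reading the output: the FPT variance profiles of the 8 trips peak at a
median radius of 665 m — the scale at which these simulated birds
concentrate their search. Of 3,132 raw fixes, 2,781 survive the sitting
filter, and 1,585 get an unambiguous travel/search label. The model
recovers the generating habitat preference: search probability rises with
the SST rank (+0.072 per rank unit, Z = 6.0) and falls (here, not yet
significantly at this small fleet size) with turbidity, while
chlorophyll-a — generated with no effect — shows none.

Useful follow-ups:

```r
tidy(report$fit)              # coefficient tibble
glance(report$fit)            # variance components, R2, logLik
autoplot(report$fit)          # partial-effect curves per covariate
plot_track_behaviour(report$behaviour)   # labelled map of the fixes
stage_counts(report)          # fixes surviving each filter
```

Tracks and rasters can equally come from disk: `pipeline_config()` accepts
a CSV of fixes (`read_tracks()` schema) and a directory of daily
single-band ASCII-grid rasters named `<variable>_<YYYYMMDD>.asc`
(`read_raster_stack()`); `write_fixture_bundle()` writes a simulation as
exactly such a tree, together with its truth record and YAML config.

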