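# moransync

Spatial synchrony and transient periodicity in multi-site occupancy
time-series.

## What it is for

Long-term wildlife monitoring often produces a handful of site-level
occupancy series — the fraction of nest-boxes or forest patches occupied
each year — observed over partially overlapping spans. For a
weakly-dispersing species such as the Siberian flying squirrel, coherent
fluctuations across sites hundreds of kilometres apart cannot be
explained by movement and instead implicate spatially correlated
environmental forcing (the Moran effect): winter weather, tree-mast
pulses, shared predator dynamics. `moransync` packages the three
statistical stages of that investigation for anyone with site-year
survey tables:

1. **Growth-rate regression.** The annual log growth rate of the
   occupancy index, `R_t = log(N_t / N_{t-1})`, is regressed on site
   fixed effects, the previous year's occupancy `N_{t-1}` (density
   dependence) and seasonal weather / food / predator covariates in
   year-`t` and year-`t-1` lag frames, with marginal F tests and VIF
   collinearity diagnostics.
2. **Synchrony correlogram.** Pairwise Pearson correlations between
   sites over their shared years, Fisher-transformed
   (`z = 0.5 ln[(1+r)/(1-r)]`) and smoothed against great-circle
   distance with a weighted penalized spline (weights = shared-year
   counts). Two permutation null models accompany the fit: a
   distance-free bootstrap giving the 95% CI of the average synchrony,
   and a Mantel-style distance-matrix shuffle giving a pointwise
   envelope and a permutation p-value on the adjusted r².
3. **Pooled wavelet spectrum.** Per-site bias-corrected Morlet power
   (`|W(s,t)|²/s`, ω₀ = 6, periods 2–8.5 y), z-scored per site, averaged
   across sites on the calendar-year axis, with a cell flagged
   significant where at least 5 sites overlap and the pooled mean
   exceeds `z₀.₉₇₅ / sqrt(count)` — localizing *transient* periodicity
   in time and period.

A first-class synthetic generator (distance-decaying multivariate
Gaussian forcing, Gompertz log-scale dynamics, binomial occupancy
observation through a logistic link) provides ground truth for every
stage; see the methods vignette in `vignettes/` for the model, the
defaults and their rationale.

## Worked example

The `analysis/` scripts run the full pipeline on a simulated 16-site
survey (ragged 5–25-year spans, winter-rain effect 0.003 per mm planted
in the dynamics):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_series.R
Rscript analysis/03_growth_model.R
Rscript analysis/04_synchrony.R
Rscript analysis/05_wavelet.R
```

which prints, for the bundled demonstration seed:

```
16 sites, 217 site-years, 199 growth-rate observations
inter-site distances 31-444 km (mean 204)

Growth-rate model (growth response), 199 observations, 181 df
        term  estimate      sd      F df_den        p vif
   rate_prev -4.135460 0.54350 57.895    181 1.46e-12   1
 winter_rain  0.000568 0.00168  0.115    181 7.35e-01   1

average synchrony r = 0.077, bootstrap 95% CI -0.018-0.172
correlogram edf 2.61, adjusted r^2 0.008, Mantel p = 0.414

16 site spectra, periods 2.0-9.0 y, years 1988-2015
567 cells with >= 5 overlapping sites; 58 significant (10.2%)
```

Reading this: growth is strongly density dependent (`rate_prev` < 0);
the single-realization winter-rain estimate is within sampling error of
the planted 0.003 (its spread across replicates, not one draw, is what
the recovery tests check); average synchrony across the 100 site pairs
is r = 0.08 with a bootstrap CI spanning zero, and the Mantel test finds
no significant distance structure for this draw — the typical outcome at
these series lengths unless the forcing correlation is strong. Tables
land in `results/`.

The same computation is available in one call:

```r
library(moransync)
cfg <- run_config(sim = sim_config(n_sites = 16, seed = 1),
                  n_perm = 5000, seed = 1)
res <- run_pipeline(cfg, out_dir = "results/run1")
res$summary
```

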