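---
title: "Methods: spatial synchrony and transient periodicity in multi-site occupancy series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial synchrony and transient periodicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Populations monitored at separate sites often fluctuate in step. When a
species disperses too little to couple distant populations — as for
boreal flying squirrels, whose natal dispersal rarely exceeds a few
kilometres — such synchrony points to spatially correlated environmental
forcing (the Moran effect): weather, pulsed food resources such as tree
mast, or shared predator dynamics. `moransync` implements the three
statistical stages used to dissect this situation in long-term occupancy
survey data:

1. a **growth-rate regression** relating the annual log growth rate of
   the occupancy index to weather, food and predator covariates with site
   fixed effects;
2. a **spatial synchrony correlogram** — pairwise Pearson correlations
   between sites, smoothed against inter-site distance with two
   permutation null models and a Mantel-type test;
3. a **pooled wavelet spectrum** — per-site bias-corrected Morlet power,
   normalized and averaged across sites, with a Gaussian cell-wise rule
   for flagging transient periodicity.

Because the field data behind such analyses are rarely deposited, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis assumes, so every stage can be tested against a
known truth.

## The data model

Surveys are long-format site-year records: `n_surveyed` units (nest-boxes
or forest patches) of which `n_occupied` showed presence. The occupancy
rate $N_t = \mathrm{occupied}/\mathrm{surveyed}$ is the abundance proxy,
and the response of the growth analysis is

$$R_t = \log(N_t / N_{t-1}),$$

defined only for consecutive-year pairs with both rates positive.
Transitions through zero occupancy are skipped with a warning rather than
patched with a pseudo-count: the monitored populations never hit zero
occupancy in practice, and a pseudo-count would inject artificial
variance into sparse synthetic series and bias the synchrony tests.

Distances between sites are great-circle (haversine) distances on a
sphere of mean radius 6371.0088 km, computed from the geographic centre
of each site. Ellipsoidal corrections are below 0.5%, well under the
resolution of any statistic here, so distance checks are read with a 1%
tolerance.

## The synthetic generator

The generator encodes the Moran-effect premise directly:

* **Forcing.** Each year an environmental noise vector is drawn from a
  zero-mean multivariate Gaussian with covariance
  $\sigma_e^2 \exp(-d_{ij}/\rho)$, where $d_{ij}$ is the inter-site
  distance. Years are independent. Defaults: $\sigma_e = 0.3$
  log-abundance units, $\rho = 200$ km — chosen so that, over the mean
  inter-site distances of a Finnish-scale network (roughly 200 km), the
  observed growth-rate synchrony averages in the 0.1–0.35 range seen in
  comparable field systems.
* **Local dynamics.** Gompertz (log-scale AR(1)) dynamics
  $x_{i,t+1} = a_i + (1+b)\,x_{i,t} + \sum_k \beta_k c_{k,i,t} + \varepsilon_{i,t}$
  with density dependence $b \in (-2, 0]$ (default $-0.5$), initialized
  at the stationary mean and preceded by a 50-year burn-in. The
  intercepts $a_i$ are derived from target equilibrium occupancy rates
  (defaults 0.05–0.18 for nest-box sites, 0.55–0.60 for pellet sites,
  matching the span of the motivating surveys).
* **Observation.** Occupancy counts are binomial:
  $\mathrm{occ}_{i,t} \sim \mathrm{Bin}(n_i,\; p_{\det}(m_i)\,
  \mathrm{logit}^{-1}(x_{i,t}))$ with method-specific detection
  (defaults 0.3 for nest-box, 0.9 for pellet surveys — tunable
  stand-ins reflecting that pellet detection is much the higher of the
  two, not field estimates). Binomial observation on counts, rather than
  Gaussian noise on rates, lets tests separate process synchrony from
  sampling noise; the logistic link keeps rates in (0, 1) while
  preserving the log-scale dynamics.
* **Ragged spans.** Each site is observed only inside its own year
  window (5–25 years by default), reproducing the 3–25 shared-year
  weighting regime of real multi-site collations.
* **Reproducibility.** One root seed; child seeds for the coordinate,
  span, forcing, covariate and observation streams are drawn
  deterministically from it, so an identical configuration is
  bit-identical in output.

An optional oscillation block adds a sinusoid (period, amplitude,
year window, site subset) to the latent state, planting transient
cyclicity for power studies of the wavelet stage.

What the generator does **not** emulate: habitat structure, dispersal
coupling between sites (deliberately absent — the analysis is about
environment-driven synchrony), observer turnover, or trends in survey
effort. Passing tests therefore demonstrate correctness of the machinery
under the Moran-effect model, not robustness to every feature of real
monitoring data.

## Growth-rate regression

The model is ordinary least squares of $R_t$ (or $N_t$ for the abundance
variant, optionally with a calendar-year trend term) on a site factor,
$N_{t-1}$, and the covariates of one lag frame. Covariates measured in
year $t$ and year $t-1$ are fitted as **separate models**, not jointly.
A Gaussian fixed-effects model needs no mixed-model machinery; the
denominator degrees of freedom are the OLS residual df, which can differ
slightly from other software's bookkeeping. Marginal (type-III) F tests
per covariate are the squared t statistics (all covariates are single
df). Collinearity is reported as VIF$_k = 1/(1 - R_k^2)$ over the
non-indicator columns, with an infinity flag for perfect collinearity.
Missing covariates are handled by complete-case deletion — the simplest
reproducible rule. No multiple-testing correction is applied across
covariates; raw per-covariate p-values are reported.

A note on the recovery experiments: the logistic observation link makes
the regression estimand $(1 - \bar p)\,\beta$ rather than $\beta$, where
$\bar p$ is the mean latent occupancy probability — the derivative of
$\log \mathrm{logit}^{-1}(x)$ is $1 - \mathrm{logit}^{-1}(x)$. The
parameter-recovery tests therefore run at low equilibrium occupancy
(0.05 under pellet detection), where the attenuation is under 10% and
inside the recovery tolerance.

## Synchrony correlogram

For every unordered site pair with at least `min_overlap = 3` shared
years (the shared-year counts of the motivating data run 3–25), the
Pearson correlation $r$ of the chosen variable over the shared years is
Fisher-transformed, $z = \tfrac12 \ln\frac{1+r}{1-r}$, clamped at
$|r| \le 1 - 10^{-6}$. The correlogram is a penalized cubic regression
spline of $z$ on distance (mgcv, basis dimension $k = 5$, smoothness by
GCV), weighted by shared-year counts; predictions are back-transformed
through $\tanh$, so fitted synchrony always lies in $(-1, 1)$. $k = 5$
suffices because empirical correlograms of this kind have effective
degrees of freedom near 1–2; when there are fewer than $k$ unique
distances the basis shrinks automatically, and below 3 a weighted linear
fit is used.

Weights enter only the smoother and the averages — the pairwise $r$
itself is the plain Pearson correlation over shared years. The average
synchrony is the weighted mean of $z$, back-transformed; averaging on
the variance-stabilized scale is the natural choice given that the whole
pipeline operates on $z$.

Two null models accompany the fit:

* **Distance-free bootstrap.** The pair list is resampled with
  replacement (weights carried), distances ignored; each draw yields a
  weighted mean $z$. The central 95% of the back-transformed means is
  the confidence interval of the average synchrony, and the same
  interval drawn flat across the distance grid is the "no spatial
  structure" band. (The alternative reading of this null — permuting
  $r$ across pairs — is available by shuffling the `z` column before the
  call; the bootstrap is the default because it also yields the CI of
  the average.)
* **Distance shuffling (Mantel).** Site labels of the distance matrix
  are permuted jointly in rows and columns; the empirical correlations
  are re-paired with the permuted distances and the spline refitted with
  the same base parameters. The pointwise envelope is the central 95% of
  the permuted predictions (read as two-sided, 2.5% per tail), and the
  adjusted Mantel p is the proportion of permuted fits whose weighted
  adjusted $r^2$ exceeds the empirical one.

The adjusted $r^2$ used on both sides of the Mantel comparison is
computed by one formula — weighted residual versus total sums of squares
with the fit's total effective degrees of freedom — so the comparison is
internally consistent. When the pair set is complete (every site pair
present), a site relabelling maps the pair set onto itself, so the
permuted distances are a reordering of the empirical ones; the
implementation exploits this to refit on a fixed design (numerically
identical to a fresh fit, verified in the tests) at a fraction of the
cost. Smoothing may also be frozen via `sp`; under GCV the selected
smoothness depends weakly on the row count, which is why "duplicating a
pair equals doubling its weight" holds exactly only at fixed `sp` (and
to about 1% under GCV).

Permutation streams for the two nulls are derived independently from the
analysis seed, and every reported p-value carries its permutation count.

## Wavelet stage

Each site's occupancy series (split at internal gaps — interpolation
would invent periodicity; segments shorter than 5 years are skipped) is
centred, scaled to unit variance, and transformed with the Morlet wavelet
$\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}$,
$\omega_0 = 6$, on log-spaced scales at 12 voices per octave covering
periods 2–8.5 years. The transform is FFT-based with the standard
frequency-domain daughter normalization; the series is zero-padded to
the next power of two **beyond the longest wavelet's support**
($n + 6\,s_{\max}$), which makes the circular convolution equal a linear
one to machine precision. The cone of influence is the e-folding time
$\sqrt{2}\,s$.

Two numerical facts worth recording:

* At periods near twice the sampling interval the Morlet peak frequency
  reaches the Nyquist frequency, where a naively time-sampled wavelet
  aliases; the FFT formulation is the standard one, and the brute-force
  convolution oracle in the tests is compared at periods ≥ 4 years where
  both formulations agree to $10^{-6}$.
* With this normalization the raw power of white noise is flat across
  scales in expectation. The scale rectification (power $|W|^2/s$, the
  bias correction) therefore does not flatten white noise; what it does
  — and what the tests verify — is give equal-amplitude oscillations at
  different periods equal peak power, removing the raw spectrum's bias
  toward long periods.

Per site, the bias-corrected power matrix is z-scored over all its cells
(sd with the $n-1$ denominator, consistent with the correlation
machinery). Normalization over all cells is the default, with a
COI-restricted variant exposed (`coi_only = TRUE`) since conventions
differ on whether out-of-COI cells should participate. The normalized
spectra are aligned on calendar years and averaged per (period, year)
cell; a cell is flagged significant when at least `min_overlap = 5`
sites contribute and its pooled mean exceeds
$z_{0.975}/\sqrt{\text{count}}$ — the upper limit of the 95% Gaussian
interval for a mean of count independent standardized values. Only the
upper tail is tested: the question is where power is significantly
*higher* than the site-wise average.

## Problem sizes and tolerances

The test-suite simulations use: 10,000 years for the forcing-correlation
Monte Carlo (±0.03 on a correlation of $e^{-1}$), 20,000 years for the
AR(1) stationary-variance check (5%), 200 outer × 500 inner permutations
for Mantel type-I calibration (binomial 95% band around 0.05), 25
replicates for Mantel power against a planted $0.5\,e^{-d/80\text{ km}}$
decay (≥ 80% rejection), 10 replicates of the 14-site planted period-3
oscillation (≥ 80% detection of a contiguous significant region), and
200 replicates of the 9-site × 20-year covariate-recovery design
(±0.0005 on a true effect of 0.003). The acceptance script runs
reduced-size versions of the stochastic studies and reports the rates it
actually measured.

## Known limitations

* The growth model is Gaussian OLS; overdispersed or heavy-tailed
  observation error would call for a robust or mixed formulation.
* The correlogram treats pair correlations as exchangeable given
  distance; pairs sharing a site are in fact dependent, which the
  bootstrap CI ignores (as does the standard field practice it mirrors).
* The Gaussian significance rule for the pooled spectrum assumes
  independent site spectra; spatially synchronous sites violate this
  mildly, inflating the flagged area when synchrony is strong.
* Period-2 cells sit at the sampling Nyquist and should be read with
  caution in any Morlet analysis of annual data.
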