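---
title: "Occupancy dynamics from passive acoustic surveys: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy dynamics from passive acoustic surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pamdyn)
```

## The problem this package addresses

A regional passive acoustic monitoring (PAM) program deploys recorders
across a grid of cells sized to the focal species' territory, runs a
neural-network classifier over the audio, and manually validates the
high-confidence predictions. The scientific questions are: what drives
where the species occurs, how do colonization and local extinction
respond to disturbance (here, high-severity wildfire), and is occupancy
trending up or down — regionally, per management unit, and inside fire
footprints? `pamdyn` implements the full chain from prediction tables to
those answers.

## From classifier output to encounter histories

Three rules turn raw predictions into data the model can use, each
motivated by a failure mode of acoustic surveys:

* **Confidence threshold, 0.989 inclusive.** Classifier confidences are
  unitless; the threshold is chosen so the retained prediction volume is
  reviewable while season-level detection probability stays high. When
  several call types pass in the same 3-second segment, only the
  highest-scoring one is kept (ties break by a fixed call-type
  precedence — four-note, contact, crow bark, monkey hoot, juvenile
  begging — purely for determinism; exact ties have probability zero in
  real scores).
* **Call-back exclusion, 1.5 km, boundary inclusive, planar Euclidean
  distance.** Broadcast surveys imitate the focal species; any
  prediction from a recorder within 1.5 km of a same-night call-back
  survey is discarded because it may be the surveyor's speaker.
* **The >= 2-nights rule.** A surveyed cell-week is coded 1 only if the
  cell accumulated at least two distinct detection *nights* across the
  whole season of that year. A single night of calling is treated as
  transient use (for a territorial species, extra-territorial movement)
  rather than occupancy. The two nights are pooled across recorders and
  across weeks; requiring them to fall in different weeks would be a
  stricter reading, and we take the minimal-assumption pooled one.

Weeks are anchored to April 1 (week 1 begins April 1 of each year;
recorders go out in early April), 18 weeks per season; nights before the
anchor or after week 18 are excluded with a warning. A "night" is
labelled by its starting date: the 20:00–06:00 analysis window spans
midnight but keeps one label. Effort is the sum of nightly recording
hours across a cell's recorders in the week; weeks with zero effort are
`NA` in the history, and a detection in a zero-effort week is a hard
error because it means the inputs are inconsistent.

## Covariates

* **Latitude** is the projected northing of the cell centroid.
* **Elevation** is residualized on latitude by ordinary least squares
  before use, because the elevational band the species occupies shifts
  along the mountain range; the residual is "elevation for that
  latitude".
* **Canopy height** enters only initial occupancy: the canopy product
  predates the monitoring period, so using it for later transitions
  would misstate post-disturbance structure.
* **Proportion burned at high severity (propHS)** is the cumulative
  fraction of the cell burned at composite burn index (CBI) >= 2.25
  (0–3 scale, 2.25 inclusive) from 1985 through the fire season
  *preceding* the year being modelled. With pixel-level burn masks the
  union over fires is computed exactly; with only per-fire scalar
  fractions the union is approximated by the complement product
  `1 - prod(1 - f)`, i.e. fires are assumed to land independently
  within the cell. The two paths coincide for a single fire; for
  multiple fires the scalar path is conservative (never exceeds the
  additive union). The transition starting in year `t` uses fires
  through year `t`; transitions are labelled by start year with the
  first as reference level.

All continuous covariates are centred and scaled over the estimation
set; quadratic terms are squares of the standardized linear column (not
re-standardized), so the pair of coefficients stays interpretable. The
per-column centre and scale are stored in the design object so new data
can be projected onto the identical scale. The "date" covariate is the
day of year at the midpoint of each week — the model needs one date per
weekly occasion and the midpoint is the unbiased choice.

## The model and its likelihood

Latent occupancy follows a two-state Markov chain over years; weekly
detections are conditionally independent Bernoulli given the state (we
assume no night-to-night correlation within a week beyond what the
weekly probability implies; nothing in the data pipeline can identify
such correlation). The site likelihood marginalizes the latent state by
a forward recursion with per-year rescaling, computed in compiled code;
a plain-R per-site implementation and an exhaustive enumeration over all
`2^T` latent sequences serve as independent oracles in the tests
(agreement to 1e-12 over 1000 random instances).

Numerical guards: linear predictors are clipped at +/-35 before the
inverse logit and probabilities floored at 1e-12 from both ends, so
likelihood and gradients stay finite even for absorbing parameter
settings.

**Priors** (all configurable via `prior_config()`): coefficients
Normal(0, 2.5); per-submodel forest intercepts Normal(mu, sigma) with
mu ~ Normal(0, 5) and sigma ~ half-Cauchy(0, 2.5). The four submodels
carry independent intercept sets — the model notation writes the same
symbol in each equation, but sharing one set across submodels would be
a much stronger assumption than the conventional independent one. The
full prior specification is recorded in each run's metadata.

## Fitting

`fit_map()` maximizes the log posterior (SDs on the log scale with the
Jacobian) by BFGS with the analytic forward–backward gradient, from
multiple starts: the first at zero, the rest drawn from the prior shrunk
by 0.2 — raw prior draws (sd 2.5 on the logit scale) start on saturation
plateaus where the gradient vanishes. Standard errors come from the
numerically differentiated observed information; because the joint mode
of a hierarchical model can sit at a collapsed random-intercept SD, the
inverse is taken on the well-identified eigenspace (eigenvalues floored
at 1e-12 of the largest) and the fit records a note when that happens.
MAP is the fast surrogate for simulation studies; the Bayesian fit is
the primary analysis.

`sample_posterior()` runs MCMC over the identical hierarchical
posterior. The engine is a discrete-latent-state Gibbs sampler (JAGS);
it is deliberately pluggable — correctness is defined by the log
posterior plus the diagnostics, and a test cross-checks the engine
against a long independent random-walk Metropolis chain over the
marginalized posterior. `warmup` maps to the adaptation phase and
`iter - warmup` draws are kept per chain; chain `c` is seeded with
`seed + c`, so runs are exactly reproducible. Defaults are 3 chains of
1500 iterations with 750 warmup. Convergence is summarized by
rank-normalized split-Rhat and bulk ESS (implemented in the package,
property-tested on constructed chains), with the pass bar Rhat <= 1.01
and ESS > 300. A Gibbs engine needs more iterations than a
gradient-based one for the same effective sample size, especially for
the hierarchical-SD block; when the bar is not met at the default
settings the fit records a warning status rather than failing, and the
remedy is simply more iterations.

## Goodness of fit

`mb_chisq_ppc()` implements the MacKenzie–Bailey chi-square as a
posterior predictive check. For each sampled draw, sites are grouped per
year and per missingness pattern; the expected count of each observed
weekly detection history is the sum over the group's sites of that
history's probability under the draw's *projected* (unconditional)
occupancy and detection probabilities; cohorts with expected count below
1e-6 and the never-observed remainder of each group are pooled. A
replicate dataset simulated from the same draw (same missingness) gives
the reference statistic, and the Bayesian p-value is the fraction of
replicates at or above the observed statistic. Well-specified data give
p away from 0 and 1; planted detection heterogeneity drives p below
0.05 (both behaviours are tested).

## Derived quantities

Trajectories are the **projected** (unconditional on the observed
detections) occupancy per draw: `psi[,1]` from the initial submodel,
then the Markov mean recursion. A data-conditioned ("smoothed") variant
would condition on each site's detections; trends use the projected one
because trend statements are about the process, not about which cells
happened to be detected. Group trajectories average cells per draw —
region, forest, or fire stratum (unburned / < 0.5 / >= 0.5 of the cell
burned at high severity, membership evaluated at a single reference
year, by default the final one, because propHS is time-varying).

`lambda_bar` is the **arithmetic** mean of the annual ratios
`psibar[t+1]/psibar[t]`, computed per draw and then summarized — that is
the defining formula, even though "annual growth rate" phrasing might
suggest a geometric mean. The probability of a declining trend is the
fraction of draws with `lambda_bar < 1`. Precision is summarized by the
mean posterior coefficient of variation of group-year occupancy, and
season-level detectability by `1 - (1 - p)^n` applied per draw.

## The synthetic-data generator

The generator exists so every downstream stage has a ground truth. Its
defaults emulate the motivating monitoring program:

* landscape: cells ordered along a ~550 km northing axis, forests as
  contiguous blocks, elevation with a latitudinal trend plus noise (so
  residualization is a meaningful step), canopy ~ Normal(22, 8) m;
* fire history: Poisson number of fires per year, contiguous-block
  footprints (mean ~6 cells; spatial realism beyond contiguity is out
  of scope since only the per-cell burned fraction enters the model),
  per-cell high-severity fraction ~ Beta(1.2, 1.8);
* dynamics preset (`owl_preset()`): baseline initial occupancy 0.30,
  colonization 0.12, extinction 0.39, weekly detection 0.6 at covariate
  means, fire effects -0.19 / -0.77 / +0.73 on initial occupancy /
  colonization / extinction, detection effort effect 0.58 — the point
  estimates of the motivating study, so recovery tests operate in the
  realistic regime;
* deployments: 2 recorders per cell, 35 consecutive nights each, 10
  recording hours per night, start uniform in the first ~13 weeks, 10%
  of cell-years skipped to create missing years;
* detections: the weekly probability is allocated uniformly across the
  distinct surveyed nights of the week
  (`p_night = 1 - (1 - p_week)^(1/n_nights)`), which reproduces the
  weekly model exactly while giving the >= 2-nights rule real nights to
  count; nights covered by two recorders count once;
* classifier output: true events get confidences in [0.989, 1];
  spurious predictions are injected per surveyed recorder-night with
  Beta(8, 1) confidences and flagged false-positive, a configurable
  fraction co-located with call-back surveys.

What the generator does **not** emulate: spatially correlated occupancy
beyond the covariates, unmodelled detection heterogeneity, classifier
confidence drift across years, partial validation (every injected
prediction carries a truth flag), and observation-level false positives
that survive validation. Passing tests therefore demonstrate the
pipeline and estimator are correct *under the model's own assumptions*,
not that the model is adequate for any particular field dataset — that
is what the goodness-of-fit check is for.

## Problem sizes used by the test suite

The oracle comparison uses 1000 random instances with up to 4 years and
5 weeks (exhaustive enumeration is exact there). Parameter recovery runs
20 replicate MAP fits at 300 cells x 4 years x 18 weeks and one full
MCMC fit at the same size; the goodness-of-fit calibration uses 20
replicates at 60 cells x 3 years with the default sampler settings.
These sizes give the recovery and calibration checks adequate power
while keeping a full test run in the tens of minutes on one core.

## Known limitations

* Site ("cell") occupancy is not territory occupancy: with randomized
  recorder placement, observed colonization and extinction rates exceed
  territory-level rates, and some site turnover reflects territory
  centers shifting rather than true loss or gain.
* False positives are assumed eliminated by validation; there is no
  misclassification submodel.
* The scalar-fraction burn-accumulation path slightly understates the
  burned proportion when real fires overlap spatially within a cell.
* The joint MAP of a hierarchical model can collapse the
  random-intercept SDs; MAP serves point recovery and simulation
  studies, while interval statements should come from the MCMC fit.
* With a Gibbs engine, the default iteration budget can leave the
  hierarchical block short of the Rhat/ESS bar; the diagnostics report
  it honestly and longer chains resolve it.
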