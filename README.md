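# pamdyn

Dynamic occupancy modelling for passive acoustic monitoring (PAM)
programs.

Large ARU (autonomous recording unit) networks produce detection data at
a scale traditional field surveys cannot match, but turning millions of
classifier predictions into defensible statements about where a species
is, how its occupancy is changing, and how disturbance drives that
change takes a long pipeline: score thresholding and manual-validation
bookkeeping, weekly encounter histories with survey-effort accounting, a
hierarchical multi-season occupancy model, and posterior summaries at
the spatial scales managers actually use. `pamdyn` implements that
pipeline end to end for a grid-cell PAM design — built around the case
of a territorial forest owl monitored across a fire-prone mountain
region — together with a synthetic-data generator that emulates every
input, so the whole chain is testable without any field data.

## The model

Cells `i` are sites, years `t` are primary occasions, and each year
holds 18 week-long secondary occasions `j`. The latent occupancy state
`z[i,t]` follows a Markov chain

```
z[i,1]   ~ Bernoulli(psi[i])
z[i,t+1] ~ Bernoulli( z[i,t] (1 - eps[i,t]) + (1 - z[i,t]) gamma[i,t] )
```

with weekly detections `y[i,t,j] ~ Bernoulli(z[i,t] p[i,t,j])` and
logit-linear submodels on standardized covariates:

```
logit(psi[i])     = alpha_NF + b1 canopy + b2 elev + b3 elev^2 + b4 lat + b5 lat^2 + b6 propHS
logit(gamma[i,t]) = alpha_NF + b1 propHS[i,t] + year dummies
logit(eps[i,t])   = alpha_NF + b1 propHS[i,t] + year dummies
logit(p[i,t,j])   = alpha_NF + b1 log(hours) + b2 date + b3 date^2 + year dummies
```

`propHS` is the cumulative proportion of a cell burned at high severity
(composite burn index >= 2.25) from 1985 through the fire season
preceding year `t`; elevation is residualized on latitude before
standardization; `alpha_NF` are forest-level random intercepts, one
independent set per submodel. The marginal likelihood sums the latent
state out by a forward recursion (compiled code, checked against an
exhaustive-enumeration oracle), and the model is fit either by MAP
(`fit_map()`, multi-start BFGS with analytic gradients) or by MCMC
(`sample_posterior()`, 3 chains x 1500 iterations with 750 warmup by
default). Derived quantities include projected occupancy trajectories,
the mean annual growth rate `lambda_bar = mean(psibar[t+1]/psibar[t])`,
probability-of-direction summaries, cumulative detection probability
`1 - (1 - p)^n`, and a MacKenzie–Bailey chi-square posterior predictive
check.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated monitoring
program (300 cells, 7 forests, 2021–2024, a 1985–2023 fire history):

```sh
Rscript analysis/01_simulate.R        # synthetic bundle under results/sim/
Rscript analysis/02_build_history.R   # predictions -> encounter history
Rscript analysis/03_fit.R             # MAP + Bayesian fit
Rscript analysis/04_trends.R          # trajectories, lambda-bar, PD, CV
Rscript analysis/05_gof.R             # posterior predictive check
```

A run with the default configuration printed:

```
simulated 300 cells, 475 fires rows, 2198 true events, 3644 predictions
latent occupancy by year: 0.27 0.283 0.327 0.307
filter ledger:
 input below_threshold segment_duplicates near_callback validated_fp retained
  3644            1319                  0            39           88     2198
agreement with simulated truth at surveyed weeks: 1.000
MAP fire effects (logit scale, standardized):
 bpsi6  bgam1  beps1
-0.149 -0.585  0.758
regional lambda-bar: 1.074 (95% CrI 1.002-1.152), P(decline) = 0.02
mean CV of forest-level annual occupancy: 0.174
  ge_0.5     lambda-bar 0.948  P(decline) 0.84
MacKenzie-Bailey posterior predictive check: Bayesian p = 0.340 (150 draws)
```

Reading it: every injected false positive is removed by the threshold /
call-back / validation filters and the rebuilt weekly history matches
the simulated truth exactly; the MAP point estimates recover the planted
fire effects (colonization down, extinction up: truth -0.77 and +0.73);
this particular simulated landscape happened to grow overall
(`lambda_bar` 1.07), while the stratum of cells burned >= 50% at high
severity declines (`lambda_bar` 0.948, probability of decline 0.84); and
the goodness-of-fit check is comfortable (Bayesian p = 0.34, far from
the 0.05/0.95 alarms).

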