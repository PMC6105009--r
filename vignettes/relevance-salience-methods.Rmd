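---
title: "Modelling subjective relevance and aberrant salience in a cued outcome-detection task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subjective relevance and aberrant salience in a cued outcome-detection task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
set.seed(1)
```

```{r load}
library(relsal)
library(dplyr)
```

# The task

The implicit salience paradigm is an outcome-detection task: on every trial a
cue appears that has two binary features — a *color* (colorful or grey) and a
*shape* (square or triangle) — and is followed by one of two outcomes, a coin
(worth 0.10 Euro) or a circle. Participants only have to press a button when
they detect the outcome; learning the cue–outcome structure is incidental.

One feature dimension is *relevant*: one of its manifestations predicts the
coin with 80% probability (and the circle with 20%), and the mapping reverses
every 20-trial block. The other dimension is *irrelevant*: both of its
manifestations are followed by either outcome equally often. After 80 of the
160 trials, the relevant dimension switches. With exact counts (the default),
every block contains 10 coins, so a session pays exactly 8 Euro.

```{r task}
task <- generate_task(isp_config(seed = 42))
task

task |>
  as_tibble() |>
  mutate(rel_manif = if_else(relevant_dimension == "color", color, shape)) |>
  group_by(block) |>
  summarise(coins = sum(outcome == "coin"),
            p_coin_rewarded = mean(outcome[rel_manif ==
                                             rewarded_manifestation] == "coin"))
```

# The learning model

Each feature dimension is tracked by its own branch of a binary hierarchical
Gaussian filter. In a branch, a level-2 Gaussian belief $\mu_2$ (the
log-odds tendency of the feature–outcome association) generates the
first-level prediction $\hat\mu_1 = s(\mu_2)$, where $s$ is the logistic
function. The branch input on a trial encodes whether the observed
feature–outcome pairing matched a fixed reference pairing of that dimension.

The update after observing input $u$ is the classic precision-weighted
prediction-error scheme: with prediction variance
$\hat\sigma_2 = \sigma_2 + \exp(\omega)$ (two-level filter) and first-level
precision

$$\hat\pi_1 = \frac{1}{\hat\mu_1 (1 - \hat\mu_1)},$$

the posterior precision is $\pi_2 = 1/\hat\sigma_2 + 1/\hat\pi_1$ and the
mean moves by $\delta_1 / \pi_2$ with $\delta_1 = u - \hat\mu_1$. In the
three-level variants a volatility level $\mu_3$ replaces the constant
log-volatility: $\hat\sigma_2 = \sigma_2 + \exp(\kappa \mu_3 + \omega)$, and
$\mu_3$ is itself updated from the level-2 volatility prediction error. Free
parameters are $\omega$ and the initial level-2 variance $\sigma_2^0$,
shared between the branches; the three-level constants are fixed
($\kappa = 1$, $\mu_3^0 = 1$, $\sigma_3^0 = 0.1$, $\vartheta = e^{-6}$).

## Relevance as first-level precision

The central quantity is the *first-level precision* $\hat\pi_1$: it is
minimal (exactly 4) at a maximally uncertain prediction of 0.5 and grows as
the prediction approaches certainty. A feature whose association with the
outcome is well learned therefore has high $\hat\pi_1$, which motivates the
definition of its *relevance weight*

$$\mathrm{rel}_\text{color} =
  \frac{\hat\pi_1^\text{color}}{\hat\pi_1^\text{color} +
  \hat\pi_1^\text{shape}},$$

with $\mathrm{rel}_\text{shape} = 1 - \mathrm{rel}_\text{color}$; a
feature's *irrelevance* weight is the other feature's relevance. All these
are prediction-time quantities, available before the outcome.

```{r traj, fig.alt = "Belief and relevance trajectories over trials"}
traj <- run_two_branch(task, learn_params(omega = -2, sigma2_0 = 0.05))
autoplot(traj)
```

## Precision-feedback variants

In the `precfb` learning variants the relevance weights feed back into
learning: the level-2 mean update of a branch is multiplied by twice its
relevance weight, $\Delta\mu_2 = 2\,\mathrm{rel} \cdot \delta_1 / \pi_2$.
The factor of two is a normalisation choice made here so that the variant
*nests* the plain filter: when both branches are equally precise
($\mathrm{rel} = 0.5$) the multiplier is 1 and the update is unchanged,
while a more relevant branch learns faster and a less relevant one slower.
An unnormalised multiplier (just $\mathrm{rel}$) would instead halve every
update at the equal-precision starting point and make the variant a
reparametrised copy of the plain filter there rather than an extension; the
test suite pins the nesting property.

# The response model

Observed reaction times are modelled on the natural-log scale,
$\log \mathrm{RT} \sim \mathcal N(\mu_t, \zeta)$, where $\zeta$ is the
noise *variance* (not standard deviation; the estimation scale is
$\log \zeta$) and

$$\mu_t = \beta_0 + \beta_1 \,\mathrm{PE}_t
  - w^\text{color}_t (\beta_2 m^\text{colorful}_t + \beta_3 m^\text{grey}_t)
  - w^\text{shape}_t (\beta_4 m^\text{square}_t + \beta_5 m^\text{triangle}_t)
  + \beta_6 \, o_t,$$

with $o_t = 1$ for circle outcomes. Four variants arise from two switches:

* **BL** — baseline: $\mathrm{PE}_t$ is the plain mean unsigned prediction
  error $(|\delta_1^\text{color}| + |\delta_1^\text{shape}|)/2$ and the
  manifestation weights $w_t$ are 1.
* **RelPE** — the prediction-error term is relevance-weighted,
  $(\mathrm{rel}^\text{color}|\delta_1^\text{color}| +
  \mathrm{rel}^\text{shape}|\delta_1^\text{shape}|)/2$ (the divisor 2 is
  kept even though the weights already sum to one, so BL and RelPE
  coefficients stay on the same scale at equal relevance).
* **IrrelBias** — each feature's manifestation bias is multiplied by that
  feature's irrelevance weight: biases towards specific manifestations only
  matter to the extent the feature is task-irrelevant.
* **RelPE+IrrelBias** — both.

The *aberrant salience* construct is captured by the composite

$$\beta_\text{irrelevance} = \tfrac{1}{2}(|\beta_2 - \beta_3| +
  |\beta_4 - \beta_5|),$$

the average within-feature asymmetry of the manifestation biases: a
reaction-time bias toward one of two equally uninformative cue
manifestations. Its raw-data counterpart, `aberrant_salience_raw()`, is the
per-half absolute difference in mean raw RT (ms) between the two irrelevant
manifestations, averaged over halves.

Crossing four learning variants with four response variants yields the
16-model space `model_space()`.

```{r sim}
sim <- simulate_subject(
  task, "2HGF-RelPE+IrrelBias",
  learn_params(omega = -2, sigma2_0 = 0.05),
  resp_params(beta0 = 6.25, beta1 = 0.2, beta2 = 0.05, beta4 = 0.03,
              beta6 = 0.07, zeta = 0.04),
  seed = 7)
subject_summary(sim)
```

# Inference

`map_fit()` maximises the log joint (response likelihood over valid trials —
responded, RT within [150, 1500] ms — plus Gaussian priors in estimation
space) with BFGS from the prior mean and seeded perturbed restarts.
Positive parameters ($\sigma_2^0$, $\zeta$) are estimated on the log scale.
The default priors are weakly informative: $\omega \sim \mathcal N(-3, 16)$,
$\log\sigma_2^0 \sim \mathcal N(\log 0.05, 1)$,
$\beta_0 \sim \mathcal N(6, 4)$, $\beta_{1..6} \sim \mathcal N(0, 1)$,
$\log\zeta \sim \mathcal N(\log 0.01, 4)$ (variances). The zero-centred
priors on $\beta_2..\beta_5$ matter for identifiability: only within-feature
*differences* of the manifestation biases are separated from the intercept
by the data, and the shrinkage resolves the remaining level/intercept
trade-off (at the cost of a small constant offset in recovered $\beta_0$).

The log model evidence is approximated by the Laplace method,

$$\log p(y \mid m) \approx \log p(y, \hat\theta \mid m)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log \det H,$$

with $H$ the Hessian of the negative log joint at the optimum. For a
linear-Gaussian submodel (e.g. intercept-only with everything else fixed)
this is exact, which the test suite verifies against the conjugate
closed form.

```{r fit}
fit <- suppressWarnings(map_fit(sim, "2HGF-RelPE+IrrelBias", n_starts = 2))
tidy(fit)
glance(fit)
```

# Model selection

Group-level comparison treats the model identity as a random effect:
population model frequencies get a Dirichlet prior and a variational
fixed point estimates their posterior from the per-subject evidences
(`rfx_bms()`). Exceedance probabilities come from Monte-Carlo Dirichlet
sampling; the Bayesian omnibus risk (BOR) compares the random-effects model
against the equal-frequency null, and the *protected* exceedance probability
blends the two: $\mathrm{pxp} = (1-\mathrm{BOR})\,\mathrm{xp} +
\mathrm{BOR}/K$. `family_bms()` aggregates frequencies over model families
(with vs without precision feedback, 2 vs 3 levels, response variants) under
a family-uniform prior.

A note on accuracy: the variational posterior frequencies are a mean-field
approximation. When per-subject evidences barely discriminate the models,
its frequency estimates can deviate from exact quadrature by a few
hundredths; with clearly separated evidences (log-evidence gaps of a few
nats) the approximation is accurate to well below 0.01, which is the regime
in which the oracle-equivalence tests pin it.

```{r bms}
L <- rbind(c(-100, -104), c(-98, -101), c(-102, -103), c(-97, -102))
colnames(L) <- c("2HGF-RelPE+IrrelBias", "2HGF-BL")
run_bms(L, n_samples = 1e5, seed = 1)
```

# Validation and its limits

`parameter_recovery()`, `model_recovery()` and
`posterior_predictive_check()` close the loop: simulate from known
parameters, refit, and compare. The default generating population
(`recovery_population()`) and the study sizes used in the validation suite
(40 subjects for parameter recovery; 10 cohorts of 20 subjects per generator
for model recovery) are this package's own desk-scale choices.

An honest caveat established by these tools themselves: at the default noise
level ($\zeta = 0.04$, i.e. a residual SD of 0.2 on log RT, about 20% of an
RT) a single 160-trial session carries limited information about several
parameters. The intercept $\beta_0$ and outcome effect $\beta_6$ recover
well ($r \approx 0.9$), but the per-subject posterior SE of $\beta_1$
(≈ 0.25) exceeds the generating population SD (0.1), the relevance weights
only span roughly 0.45–0.55 within a session, and the manifestation-bias
differences behind $\beta_\text{irrelevance}$ are of the order 0.03 on log
RT. Recovered–true correlations for $\omega$, $\beta_1$ and
$\beta_\text{irrelevance}$ are therefore low at this scale — an information
limit of the design size, not an optimiser failure (more restarts do not
change it; lowering $\zeta$ restores near-perfect recovery).

Model recovery has its own structural caveat. All four response models
share the same ten free parameters, so model comparison carries no
dimensional complexity penalty; the variants differ only through the
relevance/irrelevance weighting of existing terms. Multiplying a bias
coefficient's design column by an irrelevance weight near 0.5 halves the
likelihood curvature in that direction, and the Laplace volume term
$-\tfrac12 \log\det H$ then credits the weighted models with roughly
$\log 2$ nats per weighted coefficient per subject, while the
$\mathcal N(0,1)$ prior penalty on the correspondingly doubled coefficients
is negligible at their typical magnitudes. The practical consequence,
visible in the acceptance suite: at default noise the full model wins most
cohorts regardless of whether the data were generated by the full model or
the baseline, so a confusion analysis between these fixed-dimension
variants should not be read as complexity control.

```{r recovery, eval = FALSE}
# ~1 min; set eval = TRUE to run
rec <- parameter_recovery(n_subjects = 40, seed = 1)
tidy(rec)
autoplot(rec)
```

# Raw-data analyses

Independent of any model, `preprocess_rts()` marks valid trials,
`expectedness_means()` contrasts log RT after expected vs unexpected events
(classified from the relevant dimension only), `timebin_means()` tracks the
within-block learning curve (expected events per outcome condition, 4 bins
of 2 consecutive events, averaged over blocks), `aberrant_salience_raw()`
computes the ground-truth salience score in ms, and `group_compare()` wraps
Welch's unequal-variance test (reported as $F = t^2$), the one-sample
*t* test and Spearman's correlation for group analyses of these summaries.
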