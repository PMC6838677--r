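---
title: "Modeling cognitive offloading: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cognitive offloading: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`offloadr` models a word-pair memory task in which learners may *offload*
memory onto the environment: during study they can save up to half of each
40-pair list (20 easy, 20 difficult pairs) to the computer, and at test
they face either a *forced-recall* trial (answer from memory, +20 points
for a correct answer, -20 otherwise) or a *free-choice* trial, where they
may instead *ask for help* at an immediate cost of 3 points. Help delivers
a hint (the first two letters of the target) only if that pair was saved.
The scientific question is metacognitive: do decisions to use offloaded
information track beliefs about one's own memory?

This vignette documents the models, the tunable parameters, the synthetic
data generator, the numerical choices, and the limits of what the test
suite shows.

## The choice-and-recall model

Each free-choice trial carries a latent recall probability
$P_{rec} \sim \mathrm{Beta}(a, b)$, reparameterised by its mean and a
precision-like scalar: $a = U_{rec} V_{rec}$, $b = (1-U_{rec}) V_{rec}$.
$U_{rec}$ is *not* estimated: it is fixed at the participant's
forced-recall accuracy, which measures memory strength without help.

Asking for help is worth it when the expected value with a hint exceeds
the expected value without one. With payoffs $\pm 20$ and help cost 3,

$$E_{with} - E_{without} = 40\,P_{hint_s} - 3,$$

where $P_{hint_s}$ is the *subjective* belief in the recall boost a hint
provides. The break-even is exactly $P_{hint_s} = 3/40 = 0.075$,
independently of $P_{rec}$. Choices are linked to the rule through
near-deterministic Bernoulli probabilities (0.999 / 0.001 rather than
1 / 0) so that no single observed choice can zero out the likelihood.

Three families describe how the hint belief couples to memory strength via
$P_{hint_s} = \beta_0 + \beta_1 P_{rec}$ (clipped to $[0,1]$):

* **Constant** ($\beta_1 = 0$): the belief ignores memory strength; the
  free parameter is $\beta_0$ and the rule reduces to $\beta_0 > 0.075$.
* **Positive slope** ($\beta_1 > 0$) and **negative slope**
  ($\beta_1 < 0$): $\beta_0$ and $\beta_1$ are not separately identified
  by choices, so the families are fitted through the criterion
  $C = (0.075 - \beta_0)/\beta_1$ — ask when $P_{rec} > C$ (positive) or
  $P_{rec} < C$ (negative). Equality at the criterion resolves to
  not-ask; this is measure-zero under the continuous latent and fixed
  purely for determinism.

Recall succeeds with probability $P_{rec}$, or
$\min(P_{rec} + P_{hint_o},\, 0.999)$ when a hint was actually delivered;
$P_{hint_o}$ is the *objective* boost, estimated per difficulty only,
because hints exist only for saved pairs.

### The factorial lattice

Parameters live on the 2 (easy/difficult) x 2 (saved/unsaved) cells.
Constraint patterns tie the decision parameter across cells in four ways
(all equal; by difficulty; by saved status; all free) and the hint boost
in two (equal; by difficulty), giving 3 x 4 x 2 = 24 models for the
standard variants and 3 x 2 x 2 = 12 for the all-saved variant (`exp3`),
where saved status is not a dimension. `enumerate_model_specs()` fixes
the ordering (family, then decision pattern, then hint pattern).

### Priors and hierarchy

The hierarchical priors are this package's own choice, selected to be
weakly informative while respecting each parameter's support:
probability-scale parameters ($C$ or $\beta_0$, $P_{hint_o}$) get
logit-normal group distributions with Normal(0, 1.5^2) locations and
half-Normal(1) scales; $V_{rec}$ gets a log-normal group distribution
with a Normal(log 5, 1) location. Participant-level parameters are drawn
from their group distribution, so participants with empty cells are
shrunk to the group. Because the original prior specification for this
model class is not part of the package, fitted point estimates should be
read as approximations whose prior-induced displacement is unquantified
(small for well-identified parameters, potentially larger for
$P_{hint_o}$ in sparsely observed easy-saved cells).

### Sampling, convergence and model comparison

Models are sampled with JAGS (via `rjags`); the per-trial latent
$P_{rec}$ is sampled explicitly. Full-scale runs default to 4 chains of
100,000 iterations with the first half discarded; the test-scale preset
(`mcmc_test_config()`: 3 chains, 600 burn-in + 1,200 retained) exists for
development and continuous testing and is *not* expected to pass the
convergence screen for every parameter.

Convergence is screened with the Gelman–Rubin statistic
$\hat R = \sqrt{\hat V / W}$, computed per parameter across chains, with
the strict cut $\hat R < 1.1$. Model comparison uses
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, where the
plug-in deviance evaluates every sampled quantity — per-trial latents
included — at its posterior mean. DIC is focus-dependent; this focus
(conditional on the latents) matches what the sampler stores. The
selection rule drops screened-out fits and takes the lowest DIC, breaking
exact ties toward fewer free parameters and then lattice order. When a
test-scale run leaves *no* fit under the screen, the pipeline warns and
ranks all fits, keeping the convergence flags visible in the report.

## The confidence model

Variants other than `exp1` collect pre-test confidence ratings under
with-hint and without-hint framings. Reported confidence is modeled as

$$\mathrm{conf} \sim \mathcal N(\mathrm{clip}(P_{rec} (+ P_{hint_s}) +
\mathrm{bias},\, 0, 1),\ \sigma_{conf}^2),$$

with $P_{hint_s} = \mathrm{clip}(\beta_0 + \beta_1 P_{rec}, 0, 1)$ and
$\beta_1 = (0.075 - \beta_0)/C$ derived from the upstream criterion
rather than estimated. $\beta_0$ is constrained to $(0.075, 1)$: above
the break-even because a negative slope with a valid positive criterion
requires it, below 1 because $\beta_0$ is the hint belief at zero memory
strength. `bias` (support $(-1, 1)$, covering every non-degenerate
prediction) and $\sigma_{conf}$ are per-participant and shared across
cells; $\beta_0$ carries its own 4- or 2-pattern lattice.

Two plug-in decisions are deliberate: per-trial $P_{rec}$ and
participant-level $C$ enter as posterior means from the winning choice
model (no joint propagation of upstream uncertainty), and the Gaussian
likelihood is left untruncated even though ratings live in $[0,1]$ —
whereas the *simulator* truncates, keeping synthetic ratings on-scale.
The mismatch is second-order at the fitted noise levels
($\sigma_{conf} \approx 0.1$) except for predictions pinned at the
boundaries.

## The synthetic generator

`simulate_experiment()` generates complete experiments under the
negative-slope account (or either alternative family). Its defaults are
fixed representative values for this paradigm, chosen once:

* criteria `C`: 0.611 (easy) / 0.425 (difficult) for `exp1`-type
  cohorts, with analogous per-variant values, equal across saved status;
* objective boosts `P_hint_o`: 0.649 / 0.162 (`exp1`), again
  per-variant;
* save probabilities 0.15 (easy) / 0.75 (difficult) as independent
  Bernoulli draws per pair until the 20-pair cap — the save decision
  itself is not modeled, only its empirical rate;
* baseline recall `U_rec` by condition (easy ~0.6–0.72, difficult
  ~0.18–0.30, unsaved above saved, since learners preferentially save
  what they expect to forget), `V_rec = 5`;
* confidence intercept `beta0` per variant, `bias = 0`,
  `sigma_conf = 0.1`;
* between-participant heterogeneity on the logit scale
  (`u_sd = 0.6`, `c_sd = 0.3`, `bias_sd = 0.1`), typical of the large
  individual differences in cued recall.

Item order satisfies the presentation constraint of at most three
consecutive same-difficulty pairs (enforced by a feasibility-aware
sequential sampler, so no rejection loops); saved and unsaved items are
split randomly in half between the two test types per block; confidence
framing (with/without hint) is an unconstrained random split, since no
balancing scheme is prescribed for it. One RNG stream, seeded from the
design, is consumed in a fixed order (participant, block, learning,
test), so tables are bit-reproducible; the caller's RNG state is
restored.

What the generator does **not** emulate: response times, within-session
learning or fatigue, item-level (word-specific) effects, strategic saving
near the cap, the test-phase ordering constraint, dissociations between
confidence and performance beyond an additive bias (a second-order
metacognitive architecture is out of scope). Passing tests therefore
certify the *estimation machinery* under the model's own assumptions —
parameter recovery, model-selection recovery, oracle equivalence — not
the adequacy of the model for any real dataset.

## Numerical choices

* Latent $P_{rec}$ is truncated to $[0.001, 0.999]$ inside the sampler:
  when a sampled $V_{rec}$ pushes a Beta shape below 1 the latent density
  is unbounded at the boundary and slice sampling stalls; truncation
  bounds it with negligible effect on the marginal.
* $U_{rec}$ is clamped to $[0.01, 0.99]$ — a participant with a perfect
  or zero forced-recall score would otherwise induce a degenerate Beta.
* $U_{rec}$ stratification: per participant x condition, with the cell's
  recall count shrunk toward the participant's difficulty-level rate by 4
  pseudo-trials (`u_rec_matrix()`). A hard cell-versus-overall switch was
  considered and rejected by a parameter-recovery study: the rarest cells
  of this design (easy-saved, often 3–4 forced trials) produce raw
  fractions at the clamp boundaries, and the resulting measurement noise
  in a quantity the model treats as known visibly attenuates the
  recovered criteria. Difficulty is the dominant determinant of recall
  and each difficulty stratum holds about half a participant's forced
  trials, so it is the natural shrinkage target. Raw stratum fractions
  remain available through `compute_u_rec()`.
* The marginal per-trial likelihood (`trial_loglik_marginal`) integrates
  the latent out by adaptive quadrature, splitting at the criterion and
  at the hint cap so each piece is smooth; the test suite cross-checks it
  against closed-form incomplete-Beta expressions and brute-force latent
  simulation.
* `grid_posterior()` evaluates a single-participant, single-free-parameter
  posterior on cell midpoints under a flat prior — the independent oracle
  that the MCMC must match (total-variation distance below 0.05 in the
  acceptance suite).
* Mediation replaces a macro-based path analysis with standardized OLS
  paths and a 10,000-resample percentile bootstrap on the indirect
  effect $a \cdot b$; with collinear predictor and mediator the shared
  effect is attributed to the mediator, which reproduces the exact
  perfect-mediation limit.

## Problem sizes in the test suite

The suite favors scaled-down but statistically meaningful designs:
cohorts of 27 for parameter recovery (5 seeds, test-scale chains), 8 for
model-selection recovery (5 replicates x 3 families over a 3-spec demo
lattice), 70 (`exp1`) and 40 (`exp2a`) for behavioural-pattern and
confidence-recovery checks, and single-participant designs for oracle
equivalence. These sizes are the package's chosen compromise between the
sampling noise the assertions tolerate and a suite that runs in minutes.

## Known limitations

* The hierarchical priors are a documented substitution; exact numerical
  agreement with other implementations of this model class is not
  expected.
* The constant family is *boundary-mimicable*: a slope family with its
  criterion outside the latent's effective range reproduces any
  participant-constant choice pattern, so DIC separation on
  constant-generated data is driven by the small recall-fit distortion
  the mimicking criterion induces (and by lapse trials), not by a large
  likelihood gap. Model-recovery results for that family are accordingly
  the most fragile.
* The objective hint boost for *easy* pairs is weakly identified
  whenever baseline recall is moderate: the 0.999 recall cap saturates
  most hint trials, leaving a one-sided likelihood that lower-bounds the
  boost, and the few failure trials that would pin it down are sparse
  (easy pairs are rarely saved) and can be absorbed by participant-level
  variation in the hierarchy. Its posterior mean therefore drifts upward
  within the plateau; recovery studies show this as an overestimate of a
  few tenths at cohort sizes around 27, while the criterion parameters
  and the difficult-condition boost recover well.
* Forced-recall confidence ratings are collected by the simulated task
  but never modeled, mirroring the analysis this package implements.
* DIC is the only comparison metric (no WAIC/LOO), and the R-hat screen
  applies to stored parameters, not to per-trial latents.
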