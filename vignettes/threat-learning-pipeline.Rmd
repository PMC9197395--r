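---
title: "Modeling threat conditioning and extinction from trial-level skin conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling threat conditioning and extinction from trial-level skin conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

In Pavlovian threat conditioning, a neutral cue (the CS+) that is repeatedly
paired with an aversive outcome (the UCS — here, a fearful face with a loud
scream) rapidly comes to elicit anticipatory arousal, indexed by the skin
conductance response (SCR). A second cue (the CS−) is never reinforced, yet
responding typically generalizes to it before declining again as its safety
is learned; when reinforcement stops altogether, responding to both cues
extinguishes. Individual differences in these four processes — threat
conditioning, threat generalization, safety learning, and extinction — are
central to learning-theoretic accounts of anxiety.

`threatlearn` implements a complete, testable pipeline for quantifying these
processes from trial-level SCR data: amplitude scoring and cleaning,
trial-by-trial associative-learning models, per-subject least-squares
fitting with BIC model comparison, parameter- and model-recovery
simulation, and association analyses linking fitted learning parameters to
anxiety severity, age, and subcortical gray-matter volume (GMV) with
permutation-based family-wise error control. Because trial-level clinical
datasets of this kind are rarely shareable, the package includes a
first-class synthetic-cohort generator that emulates the task and the
statistical structure the analyses assume, so every stage of the pipeline is
exercised end to end without external data.

## Task structure

The task has three phases per subject: 4 pre-conditioning (habituation)
presentations per CS, 10 conditioning presentations per CS with 8 of the 10
CS+ trials reinforced (an 80% partial-reinforcement schedule), and 8
unreinforced extinction presentations per CS. `build_task_schedule()`
constructs the trial list; CS+ and CS− trials are pseudo-randomly
interleaved with at most two consecutive same-CS presentations, in two
counterbalance orders (A/B). Two choices the task description leaves open
are fixed here: the run-length cap of 2 operationalizes
"pseudo-randomized", and the two unreinforced CS+ positions are drawn once
per counterbalance order from trials 2–10, so that learning always begins
on a reinforced trial. Inter-trial intervals are not modeled; the pipeline
is trial-indexed throughout.

```{r}
library(threatlearn)
sch <- build_task_schedule("A", seed = 1)
table(sch$phase, sch$cs)
```

## The model family

Fourteen model variants are registered (`model_registry()`). Models 1–8 are
Rescorla–Wagner (RW) variants. On each reinforced CS+ conditioning trial,
the prediction error is

\[ \delta(t) = r(t) - v_{CS+}(t), \]

where \(r(t)\) is the *observed SCR to the UCS* on that trial (not a 0/1
indicator: UCS responses diminish across acquisition, and their magnitude
carries the scale of the conditioned response). Both cue values are then
updated,

\[ v_{CS+} \leftarrow v_{CS+} + \alpha_{CS+}\,\delta, \qquad
   v_{CS-} \leftarrow v_{CS-} + \alpha_{CS-}\,\delta, \]

the second equation carrying threat generalization: the never-reinforced
CS− inherits CS+ prediction errors at its own rate. Optional features
combine to give the family:

* **Learning inertia** (models 2, 5, 6, 8): the update uses the sum of the
  current and the `km` preceding prediction errors; `km = 2` is fixed
  population-wide.
* **Learning-rate decay** (3, 5, 7, 8): the effective rate on the *t*-th
  update event is \(\alpha/\sqrt{t}\), so early encounters dominate. The
  decay clock counts update events within the phase, starting at 1 (the
  source material does not say whether the clock indexes trials or updates;
  updates is the reading under which the rate applies \(\alpha\) on the
  first update, as the closed form requires).
* **Response habituation** (4, 6, 7, 8, 14): the *emitted* prediction is
  multiplied by \(e^{-\varphi_{CS}[t - t_0]^+}\) with the per-CS trial
  index \(t\) and \(t_0 = 2\) fixed population-wide; the latent value used
  in subsequent updates is left untouched. A `hab_latent` switch in
  `model_options()` applies the factor to the latent value as well, for
  sensitivity checks.

Model 9 is an RW/Pearce–Hall hybrid: values update as
\(v \leftarrow v + \kappa\,\alpha_{PH}\,\delta\) with a fixed per-CS rate
\(\kappa\) and an adaptive associability
\(\alpha_{PH} \leftarrow \gamma|\delta| + (1-\gamma)\alpha_{PH}\),
initialized at 1. As printed, the hybrid value-update rule omits
\(\delta\); it is implemented with the signed \(\delta\) driving the value
update and \(|\delta|\) driving only the associability update, the reading
consistent with the surrounding text and with the hybrid-model literature.
Models 10–12 wrap the same machinery with binary reinforcement
(\(b_{UCS} \in \{0, 1\}\), prediction errors on every CS+ trial) and a
linear read-out: predicted SCR is \(\beta_0 + \beta_1 V\) (model 10),
\(\beta_0 + \beta_1 \alpha_{PH}\) (11), or
\(\beta_0 + \beta_1 V + \beta_2 \alpha_{PH}\) (12).

Models 13–14 are Beta–Bernoulli uncertainty models: per CS, pseudo-counts
start at Beta(1, 1) and update by \(u(t) \in \{0,1\}\) (UCS delivered or
not) each time that CS is shown; the emission is
\(\beta_0 + \beta_1 z_{CS}(t)\) with
\(z_{CS}(t) = h_{CS}(t) + \mathrm{E}[\theta]\) and
\(h_{CS}(t) = -\ln(\alpha_B + \beta_B)\), exactly as the model table
prints it. Note that this \(h\) depends only on the number of observed
trials of that CS, not on outcomes; whether the original uncertainty model
intended a variance-based surprise term is unresolved, so a
variance-based alternative (\(h = \ln \mathrm{Var}[\theta]\)) is available
via `model_options(h_form = "variance")`, with the literal form as the
default. Because no UCS is ever delivered in extinction these models would
never update there; requesting them for extinction is an error.

**Initialization.** Both cue values start at \(v_i\), the last
pre-conditioning SCR for conditioning fits and the first extinction-phase
SCR for extinction fits (the last/first *non-missing* value if cleaning
left gaps); associabilities start at 1 and Beta counts at (1, 1).

**Extinction.** During extinction no UCS occurs. Each CS trial generates an
omission prediction error \(\delta = 0 - v_{CS}\) that updates that CS's
value with its own learning rate, with the decay/inertia/habituation
features applied per CS. Under this scheme the base model decays
geometrically, \(v(t+1) = (1-\alpha)v(t)\), separate CS+ and CS−
extinction rates are identifiable, and negative rates describe paradoxical
response growth — which is why extinction fits bound the rates to
\([-1, +1]\). This is the only reading under which per-CS extinction rates
(and their occasional pinning at the bounds) are meaningful; a literal
"no UCS, no update" reading would leave extinction predictions constant
and the rates unidentifiable.

One family-level caveat: with a constant reinforcer and moderate rates the
non-inertia models approach \(r\) monotonically, but the inertia variants
do not in general — the window re-applies stale large errors after the
value has caught up, producing overshoot-and-return. The property tests
cover the monotone members only.

## Fitting and model comparison

`fit_subject()` minimizes the sum of squared differences between predicted
and observed SCR over the model's free parameters with Nelder–Mead simplex
search, restarted from a grid of learning-rate initial values
\(\{0.1, \dots, 0.8\}\) (other parameters start at \(\varphi = 0.1\),
\(\gamma = 0.5\), \(\beta_0 = 0\), \(\beta_1 = 1\), \(\beta_2 = 0\); the
uncertainty models, which have no learning rate, vary \(\beta_1\) over the
grid). The best restart by SSE wins; restarts within tolerance of the best
are resolved toward the smallest parameter norm, so degenerate flat data
yield \(\alpha = 0\) rather than an arbitrary zero-SSE representative.
Conditioning fits are unconstrained; extinction fits clip learning-rate
parameters to \([-1, +1]\) inside the objective and flag
`pinned_at_bound` when the unconstrained optimum lies outside.
Convergence uses a relative SSE tolerance of 1e-8 with at most 2000
evaluations per restart; non-convergence is reported, not raised.

Model fit is summarized per subject by a Gaussian-residual BIC, computed
exactly as the source procedure defines it:

\[ \mathrm{BIC} = -k\ln(n) + n\ln(\mathrm{variance}), \]

with \(k\) free parameters, \(n\) fitted points (20 for conditioning, 16
for extinction), and variance = RSS/n. The sign of the complexity term is
the opposite of the conventional BIC penalty — as written, each extra
parameter *lowers* the criterion by \(\ln n\) — and `compute_bic()`
implements it as printed, with `convention = "standard"` available for
sensitivity analyses. `compare_models()` reports per-model means and
standard errors, best-model fractions, a repeated-measures ANOVA on BIC
(model fixed, subject random), and Bonferroni-corrected pairwise paired
t-tests; the winning model is the best-scoring one unless a simpler model
is statistically indistinguishable from it, in which case the simplest
such model is preferred.

## Recovery

`parameter_recovery()` draws generating parameters (by default uniform over
plausible ranges: learning rates 0.05–0.9, \(\varphi, \gamma\) 0–1,
\(\beta_0\) ±0.5, \(\beta_1, \beta_2\) 0.1–2), simulates a series per draw
with fresh UCS responses and Gaussian observation noise clamped at zero,
refits, and correlates generating with recovered values. A model is
*recoverable* when every parameter's Pearson correlation reaches 0.20;
undefined correlations count as failures. When no noise level is given,
the noise sd is set to 25% of the mean noiseless signal range across the
drawn parameter sets ("moderate noise"). `model_recovery()` crosses
generating and fitted models into a BIC-selection confusion matrix. The
short schedule limits identifiability by design: the 2-parameter RW model
recovers comfortably (correlations ≈ 0.8 at moderate noise), while the
heavily parameterized read-out variants degrade — the motivation for
restricting model comparison to recoverable models.

## SCR preprocessing

`score_trial_amplitude()` scores a trial as the square root of the
(non-negative) base-to-peak conductance difference within 1–5 s after
stimulus onset. `clean_series()` applies the cleaning rules per CS and per
phase: within-subject outliers beyond `outlier_sd` sample SDs are set
missing; the exclusion decision (more than 50% of a phase's trial values
missing) is made on pre-interpolation missingness; interior gaps of up to
three consecutive trials are linearly interpolated (via `zoo::na.approx`);
and trailing conditioning / leading extinction gaps are linearly
extrapolated through the two nearest valid points, clamped at zero. One
arithmetic note: in a cell of \(n\) values the sample z-score cannot
exceed \((n-1)/\sqrt{n}\) — 2.85 for the 10-trial conditioning cells —
so the conventional \(|z| > 3\) within-subject cut can never fire at this
task's cell sizes; it is kept (and parameterized) because the operative
outlier control at this scale is the group-level rule,
`flag_group_outliers()`, which excludes subjects whose per-CS mean
response lies beyond 3 SDs of the group.

## Association analyses

Anxiety severity is harmonized across age groups by
`combine_anxiety()`: youth scores are the mean of child- and parent-report
SCARED totals, adults use the STAI trait score, and each instrument is
z-transformed within its own age sample before concatenation.

`param_anxiety_regression()` fits, for one fitted learning parameter,
`parameter ~ anxiety + age + anxiety:age` on z-scored variables and flags
terms against the family-wise Bonferroni threshold (0.05/4 = 0.0125 for
the four conditioning parameters, 0.05/2 = 0.025 for the two extinction
rates — both CS rates are tested, whatever the verbal description of the
family). Adjustment covariates support specificity analyses (e.g.
controlling for the CS+ habituation rate).

`gmv_moderation()` tests, per subcortical structure, the anxiety-by-GMV
interaction on a learning parameter in
`parameter ~ anxiety * gmv + sex + icv` (sex and total intracranial
volume as nuisance). Family-wise error over the structure family is
controlled by a Freedman–Lane-style permutation max-statistic: residuals
of the reduced (interaction-free) model are permuted with the same
permutation applied to every structure, and the maximum absolute
interaction t across structures forms the null. Significant interactions
are decomposed as anxiety simple slopes at GMV ±1 SD. Vertex-wise
cortical analyses are out of scope; the structure-level max-statistic
family plays the corresponding role for subcortical volumes.

Both second-level functions exclude, in a single pass, subjects whose
parameter estimate lies beyond 3 sample SDs of the group
(`param_outlier_sd`, set `Inf` to disable). Unconstrained per-subject
least-squares estimates are heavy-tailed: when a CS− series is crushed to
the zero-clamp, the habituation rate is unbounded above and its estimate
can escape to arbitrarily large values that are genuine SSE minima. A
handful of such estimates dominates any standardized association, so the
same conservative \(|z| > 3\) principle used for raw SCR group outliers
is applied to the estimates entering group-level models.

`raw_scr_anova()` computes per-subject phase × CS mean SCR and fits the
2 × 2 within-subject ANOVA with anxiety and (centered) age as continuous
between-subject covariates via `aov` with `Error(subject/(phase*cs))`
strata, plus per-phase CS-effect follow-ups.

## The synthetic-cohort generator

`simulate_cohort()` generates, per subject: age (uniform 8–50), sex,
anxiety z-score, intracranial volume with a sex effect, and seventeen
subcortical structure volumes (bilateral amygdala, hippocampus, thalamus,
ventral diencephalon, caudate, putamen, pallidum, nucleus accumbens;
brainstem) built from shared ICV/sex loadings plus a structure-specific
factor. Responses are scaled by an age-dependent amplitude factor (older
subjects respond less), pre-conditioning trials habituate, UCS responses
decay exponentially across reinforced trials, conditioning data come from
the design's generating model (model 7 by default — the RW variant with
learning-rate decay and habituation, whose four parameters are the CS+
threat-learning and habituation rates and the CS− generalization and
safety-learning rates), and extinction data from model 3. Trial-level
Gaussian noise is clamped at zero and missingness is injected per trial.
Ground-truth parameters are stored alongside (`true_*` columns).

Two couplings are planted. The anxiety→safety-learning coupling (default
−0.3 standardized, on the *true* CS− habituation rate) and a GMV
moderation of that coupling (default 0.5), planted on the
*structure-specific* volume factor of the left accumbens: planting on the
full volume z-score would load the moderation onto the ICV/sex components
shared by every structure, turning "accumbens-only" into a diffuse
anxiety-by-ICV interaction. Defaults were set so that the *observed*
effects — after the attenuation that per-subject fitting necessarily
introduces (the fitted safety-learning rate correlates ≈ 0.5–0.8 with its
generating value under the default noise) — land at the scale reported
for studies of this size: a standardized anxiety β near −0.2 and a
moderation detectable under family-wise correction around n ≈ 150–200.
Between-subject parameter spreads (e.g. safety-learning rate mean 0.35,
sd 0.25) were likewise chosen so that true inter-individual variation is
not swamped by estimation error. Observation noise defaults to 0.12
sqrt-µS per trial and missingness to 2% of trials.

What the generator does *not* emulate: continuous conductance waveforms
(the canonical input is trial-level scores; `score_trial_amplitude()`
covers waveform scoring separately), temporal autocorrelation of SCR
noise, non-Gaussian response distributions, instrument-level anxiety item
structure, and any real neuroanatomical covariance beyond the shared
ICV/sex loadings. Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes, not that real SCR data satisfy those
assumptions.

## Numerical choices and degenerate inputs

Restart ties are resolved toward the smallest parameter norm; variance at
or below zero is floored at machine-epsilon scale (with a warning) before
the BIC logarithm; zero-variance cells yield no outliers; a constant GMV
column is skipped with a message; permutation p-values use the
\((1 + \#\{\cdot\})/(B + 1)\) estimator, so a single permutation bounds
the corrected p at 1; an instrument group with fewer than two members
makes the within-group z-transform undefined and raises an error; an
all-missing series is excluded with a reason rather than fit.

## Problem sizes

The test suite exercises the pipeline at sizes chosen to make its
statistical checks sharp but quick: recovery at 100 simulations (60 per
point on the noise-monotonicity grid), null calibration of the
permutation FWE over 200 replicate cohorts of 60 subjects with 199
permutations, and the planted-effect pipeline over 3 replicate cohorts of
200 subjects with 799 permutations. The acceptance script reruns the
recovery benchmark at 100 simulations from a user-supplied seed.

## Limitations

Parameter estimation from 20 conditioning trials is intrinsically noisy;
the heavily parameterized variants (10–12 especially) are not recoverable
at this scale and are excluded from comparison by the recovery criterion
rather than by fiat. Hierarchical (partial-pooling) estimation would
reduce first-level variance but is out of scope. The printed BIC's
complexity reward, the literal count-based uncertainty term, and the
omission-error extinction scheme are all implemented as specified with
documented switches or error paths; users comparing against conventional
implementations should mind those three points in particular.
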