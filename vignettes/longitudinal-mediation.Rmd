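---
title: "Longitudinal causal mediation for PD non-motor symptoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal causal mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmed)
```

## The scientific problem

REM sleep behavior disorder (RBD) is among the most burdensome non-motor
symptoms of Parkinson's disease. Beyond its direct impact on daily life,
RBD is suspected to erode activities of daily living (ADL) *indirectly*,
by worsening depression and accelerating cognitive decline. Quantifying
how much of the RBD–ADL effect travels through these two mediators — and
how that mediated share evolves over the disease course — requires
longitudinal causal mediation methods rather than a single cross-sectional
mediation model.

`longmed` implements two complementary analyses over a nine-visit annual
panel of four rating scales — RBDSQ (exposure $X$, 0–13), GDS-15
(depression, mediator $M_1$, 0–15), MoCA (cognition, mediator $M_2$,
0–30, higher is better) and MDS-UPDRS Part II (ADL, outcome $Y$, 0–52) —
plus baseline covariates (sex, age band, education band, race, family
history, disease-duration band):

1. a **Bayesian dynamic mediation model** per single mediator, with
   time-varying path coefficients and an indirect-effect curve
   $\mathrm{IE}(t) = \alpha(t)\,\beta(t)$; and
2. a **mediational g-formula** for both mediators jointly, with a
   two-way decomposition (total, direct, joint indirect, residual $\xi$)
   and a path-specific decomposition, bootstrap intervals, and a Monte
   Carlo power analysis.

Visit indices $k = 0,\dots,8$ are mapped to normalized study time
$t = k/8 \in [0,1]$ by min–max normalization, so the conventional
reporting timepoints $t = 0.25, 0.50, 0.75$ are follow-ups 2, 4 and 6.

Real cohort data of this kind live behind registration walls, so the
package ships a synthetic cohort generator with *known* mediation
structure; every modeling claim in the package is validated against that
known truth or against exact oracles.

## The synthetic cohort generator

`dgp_config()` / `simulate_cohort()` draw panels from the linear
time-varying-coefficient mediation model

$$M_{j,ik} = a_j(t_{ik}) + \alpha_j(t_{ik})\,X_{ik} + \gamma_j' C_i +
  u^{M_j}_i + \varepsilon_{j,ik},$$
$$Y_{ik} = b_0(t_{ik}) + \textstyle\sum_j \beta_j(t_{ik})\,(M_{j,ik}-c_j)
  + \tau(t_{ik})\,X_{ik} + \gamma_Y' C_i + u^{Y}_i + \varepsilon'_{ik},$$

with exposure a rounded, range-truncated Gaussian AR(1) process
($\rho = 0.7$, mean 4, SD 2.5 — repeated measures of a fairly stable
trait), independent subject random intercepts, Gaussian residuals, and
baseline covariates drawn from the marginal frequencies typical of an
early-PD cohort (about two-thirds male, three-quarters over 65,
predominantly White). The mediators are conditionally independent given
$(X, C)$, so each single-mediator analysis is correctly specified even
though the outcome depends on both.

Defaults are fixed once and define the package's study conditions:

* 337 subjects, 9 annual visits;
* affine increasing paths, e.g. $\alpha_1(t) = 0.10 + 0.16t$,
  $\beta_1(t) = 0.35 + 0.25t$ for depression, and negative path pairs
  for MoCA (worse RBD lowers cognition, lower cognition raises ADL
  limitation), giving positive indirect effects on the harm scale that
  roughly **double between $t=0.25$ and $t=0.75$** — the qualitative
  growth pattern this class of studies reports;
* direct path $\tau(t) = 0.25 + 0.10t$;
* random-intercept SDs (1.2, 1.5, 2.0) and residual SDs (1.5, 1.8, 2.5)
  chosen so pooled correlations among the four scales land in the
  0.1–0.4 band typical of non-motor symptom batteries;
* score clipping (round + truncate to the scale ranges) on by default.

The mediator centering constants $c_j$ only shift the outcome intercept;
they keep simulated UPDRS-II scores in a realistic low range.

What the generator does *not* emulate: item-level responses, informative
dropout, floor/ceiling mixtures beyond simple clipping, practice effects
on MoCA, or medication-state effects on UPDRS-II. Passing tests on this
DGP therefore demonstrate correctness of the estimators under the stated
model, not robustness to every feature of registry data.

Because clipping rounds and truncates the latent Gaussian scores, it
attenuates the realized paths relative to the configured
$\alpha_j(t)\beta_j(t)$; the analytic `true_effects()` curve is the
estimand of the *unclipped* model. Parameter-recovery and coverage
experiments therefore run with `clipping = FALSE`, where the fitted
model is exactly correctly specified; the clipped default is used
everywhere realism matters more than a known truth.

Seeding is per subject: subject $i$'s stream is a deterministic function
of the master seed and $i$, so enlarging the cohort extends it without
reshuffling existing subjects.

`simulate_toy_discrete()` generates fully discrete one- or two-visit
binary toys from explicit conditional probability tables, retained with
the panel so that the g-formula can be enumerated exactly.

## The Bayesian dynamic mediation model

For one mediator $M$, `fit_dynamic_mediation()` samples the two-equation
model

$$M_{ik} = a_0(t) + \alpha(t) X_{ik} + \gamma_M' C_i + u^M_i +
  \varepsilon^M_{ik}, \qquad
  Y_{ik} = b_0(t) + \beta(t) M_{ik} + \tau(t) X_{ik} + \gamma_Y' C_i +
  u^Y_i + \varepsilon^Y_{ik}.$$

$\alpha(t)$ is the time-varying effect of exposure on the mediator,
$\beta(t)$ the effect of the mediator on the outcome adjusted for
exposure, and $\tau(t)$ the adjusted direct path (included because the
outcome equation must adjust for $X$ even though only the two mediation
paths enter $\mathrm{IE}(t)$).

**Basis.** All five coefficient curves share one basis of normalized
time: a cubic B-spline with 5 degrees of freedom on $[0,1]$ (default),
or `basis = "linear"` ($1, t$). Nine distinct timepoints support df = 5
comfortably while keeping the curves as smooth as the slowly evolving
clinical processes they describe; the linear option is the right choice
for simulation studies where the generating paths are affine and for
small samples.

**Priors and sampler.** On standardized data (default `standardize =
TRUE`: $X$, $M$, $Y$ z-scored), all basis weights and covariate effects
get $\mathcal N(0, 2^2)$ priors; residual variances
$\mathrm{IG}(2, 1)$ and random-intercept variances
$\mathrm{IG}(2, 0.5)$. With these choices every full conditional is
conjugate, and the two equations share no parameters, so their
posteriors factorize and are sampled by an exact **blocked Gibbs
sampler** (coefficient block, subject intercepts, variances). Inverse
gamma rather than half-normal variance priors is a deliberate trade:
exact conjugacy buys fast, tuning-free sampling, and with hundreds of
subjects the variance posteriors are data-dominated. Chains are
initialized at a jittered least-squares solution, and each chain's RNG
stream is derived deterministically from the seed, so fits are exactly
reproducible and invariant to row order and subject relabeling.

Defaults are 10,000 iterations per chain (5,000 warmup) and 4 chains;
the retained posterior has $\text{chains} \times (\text{iter} -
\text{warmup})$ draws. The test suite and replication script run the
same sampler at 900–5,000 iterations with 2 chains — at roughly 1 ms per
iteration this keeps each fit to seconds, and split-$\widehat R$ stays
below 1.05 because the conjugate blocks mix quickly.

**Reporting.** `indirect_effect_curve()` forms $\alpha(t)\beta(t)$ draw
by draw (the equations' posteriors are independent given the data, so
pairing draws by index is valid), then reports the posterior mean,
posterior SD and equal-tailed 95% credible interval per grid point. On
the standardized scale the IE magnitudes land in the 0.02–0.15 range
familiar from published mediation tables; `scale = "raw"` multiplies by
$\mathrm{sd}(Y)/\mathrm{sd}(X)$ to recover ADL points per exposure
point. The reported "SD" is the posterior SD of $\mathrm{IE}(t)$, not a
Monte Carlo standard error.

**Diagnostics.** `diagnose()` computes split-$\widehat R$ (chains halved)
and effective sample size per scalar parameter, flagging
$\widehat R > 1.05$ or $\mathrm{ESS} < 400$; constant chains yield `NA`
and a flag rather than an error. Fits warn at fit time when any
$\widehat R$ exceeds 1.05.

**Validation.** The sampler is cross-checked in the test suite against
an independent REML route (`lme4::lmer` with basis-interaction fixed
effects), against per-visit OLS products of coefficients, and in a
20-replicate experiment at $n = 337$ that requires $\ge 80\%$ empirical
coverage of the true $\mathrm{IE}(t)$ at $t \in \{0.25, 0.5, 0.75\}$ and
a null IE flagged in $\ge 90\%$ of null-path replicates. Those
replicate counts keep the experiment to a couple of minutes; they bound
coverage loosely rather than pinning the nominal 95% rate, which would
need hundreds of replicates.

## The mediational g-formula

For both mediators jointly the package estimates interventional effects
under sustained exposure regimes by g-computation
(`fit_component_models()` + `decompose_twoway()` /
`decompose_pathspecific()`).

**Component models** (all `stats::lm`, linear Gaussian by default):
each mediator at baseline and at follow-up visits — follow-up models
include visit dummies, the current exposure, one-visit lags of the
exposure and of both mediators, and baseline covariates; the final-visit
outcome given final exposure and mediators plus covariates; and an
**anchor model** of the outcome on exposure history only (current plus
mean prior exposure). Responses observed to be 0/1 are simulated as
Bernoulli, which makes saturated linear-probability fits exact on the
binary toys. Since the covariates are baseline-fixed, "covariate history
up to $t$" reduces to baseline adjustment plus the lagged analysis
variables. Zero-variance predictors are dropped; a constant response is
flagged as degenerate; rank deficiency is an error naming the model.

**Counterfactual engine.** `n_mc` pseudo-subjects (default 10,000)
resample baseline covariates from the panel and are simulated forward
through the mediator cascade under per-role exposure assignments: the
models of each mediator, and the outcome model, can each see the high
regime $\bar x_h$ or the low regime $\bar x_l$. The default contrast is
data-adaptive — the per-visit 90th versus 10th percentile RBDSQ
trajectory, a concrete "sustained worsening" — and fully configurable.
All regimes share **common random numbers** (one set of residual draws
and covariate indices per decomposition), which removes between-regime
Monte Carlo noise from every contrast.

With $s(\cdot)$ the mean simulated outcome under an assignment:

* total (model) effect: $\mathrm{TE}_{\text{model}} = s(hhh) - s(lll)$;
* direct effect: $\mathrm{DE} = s(llh) - s(lll)$ (only the outcome model
  sees the high regime);
* joint indirect effect: $\mathrm{IE}_{\text{joint}} = s(hhh) - s(llh)$;
* path-specific contributions: sequential switches in the declared
  mediator order (depression before cognition by default, reflecting
  that depressive symptoms typically precede measurable cognitive
  decline), each contribution being the change when that mediator's
  models switch from low to high with earlier mediators already
  switched.

Common random numbers and telescoping sums make
$\mathrm{TE}_{\text{model}} = \mathrm{DE} + \mathrm{IE}_{\text{joint}}$
and $\mathrm{IE}_{\text{joint}} = \sum_j \mathrm{IE}_j$ hold to machine
precision on every run; the interaction remainder is reported and is
zero by construction under this cascading definition. A mediator not
declared in the spec has its models tied to the outcome's regime, so its
response to exposure counts as part of the direct path — the standard
interventional-effect convention for "other" mediators.

**The residual $\xi$.** The reported total effect is taken from the
*anchor* model (g-formula without mediators), and
$\xi = \mathrm{TE} - (\mathrm{DE} + \mathrm{IE}_{\text{joint}})$
measures the discrepancy between that unmediated estimate and the
mediational model's decomposition. The identity
$\mathrm{TE} = \mathrm{DE} + \mathrm{IE}_{\text{joint}} + \xi$ is exact
by construction, and $\xi$ is an honest misspecification signal: it is
zero (up to sampling noise) on correctly specified linear toys and on
CPT-backed models, and grows when, e.g., score clipping makes the true
regression functions nonlinear so that the reduced-form and mediational
routes extrapolate a wide sustained contrast differently. Percentage
shares divide by this anchored TE and are reported as undefined when
TE is zero.

**Exact oracle.** `enumerate_oracle()` computes the same decomposition
for the discrete toys by exhaustive summation over the binary mediator
trajectories (state spaces capped at $10^6$), with identical regime
semantics. The engine is required to agree with it within 0.005
absolute at $n_{mc} = 10^6$, and the error is checked to shrink with
$n_{mc}$.

**Uncertainty.** `gformula_bootstrap()` resamples subjects with
replacement (default 500 replicates), refits everything per replicate
and returns percentile 95% intervals. The exposure contrast is resolved
once on the original panel and held fixed so that the intervals reflect
sampling uncertainty of the effects, not drift of the contrast
definition. Failed replicates are counted; more than 10% failing is an
error.

## Monte Carlo power analysis

`estimate_power()` answers the post-hoc question "at this sample size,
how often would indirect effects of the observed magnitude be
detected?". The DGP is calibrated per mediator by holding the outcome
path at the default mid-study value and solving the exposure path so
that $\alpha_j\beta_j$ equals the target mean indirect effect (defaults
0.068 and 0.095, with clipping off so the calibration is exact and
always solvable for finite targets; a zero target therefore means a zero
exposure path with a nonzero outcome path, the boundary null).

Per replicate the default engine collapses subjects to visit means
(subject random intercepts then only inflate residual variance, so OLS
across subjects is valid), estimates the two paths, and tests each
indirect effect with a **Monte Carlo confidence interval**: percentiles
of $a^* b^*$ over draws from the estimated sampling distributions of the
path coefficients (with the outcome-path covariance preserved for the
summed effect). This interval-excludes-zero criterion holds its nominal
5% size under the boundary null — the delta-method (Sobel) interval does
not, being conservative for products — and the test suite verifies the
size at 500 replicates within three binomial Monte Carlo standard
errors. A `dynamic_bayes` engine runs the full Bayesian model per
replicate instead (credible interval excludes zero); it is provided for
fidelity checks at small `n_reps`.

Power is reported per mediator and for the summed indirect effect, with
$\sqrt{p(1-p)/n_{\text{reps}}}$ Monte Carlo standard errors; it is
checked to be nondecreasing in sample size and effect magnitude on a
3×3 grid at 300 replicates per cell.

## Numerical and design choices, in brief

* **Missing data**: complete-case per subject-visit
  (`complete_case_filter()`), with per-variable removal counts reported;
  the rule is explicit so alternatives can be slotted in upstream.
* **Categorization cut-offs**: GDS-15 $\ge 5$ mild, $\ge 10$
  moderate–severe; MoCA $\ge 26$ normal. Boundaries are tested at
  4/5, 9/10 and 25/26.
* **Dummy coding** uses the modal category of each covariate as
  reference.
* **Equal-variance t-test / classic one-way ANOVA** for baseline ADL
  comparisons (matching the single-statistic layout such tables use),
  pooled-scope Pearson correlations by default, and no multiple-testing
  correction (documented in the output rather than silently applied).
* **Degenerate inputs**: constant exposure or mediator is an error for
  the dynamic model; zero-variance variables yield flagged undefined
  correlations; identical groups give $t = 0, p = 1$; empty
  complete-case results raise a "no analyzable data" error.
* **Problem sizes** in the shipped tests and replication script — 337
  subjects, 2-chain fits of 900–5,000 iterations, $n_{mc}$ of
  $10^4$–$10^6$, 200–2,000 power replicates, 20-replicate coverage
  experiments — were chosen as the smallest sizes at which each check is
  statistically meaningful, and are stated alongside each result.

## Known limitations

* The dynamic model assumes Gaussian errors and linear score effects;
  bounded integer scales with floor effects (low GDS-15 in early PD)
  attenuate paths relative to the latent linear model. Non-Gaussian
  outcome families are out of scope.
* Random intercepts only; random slopes and within-subject residual
  autocorrelation beyond the exposure process are not modeled.
* The g-formula's identification requires no unmeasured
  exposure–mediator or mediator–outcome confounding given baseline
  covariates and the lagged history; the path-specific decomposition
  additionally leans on the declared mediator ordering wherever the
  mediators interact (order sensitivity is tested to vanish for
  independent mediators).
* $\xi$ flags misspecification but does not locate it.
* The power module's printed defaults target mean indirect effects on
  the raw scale of its own DGP; power for the full g-formula
  decomposition (bootstrap within simulation) is intentionally not
  offered at desk scale.
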