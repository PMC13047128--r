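# longmed — longitudinal causal mediation for Parkinson's non-motor symptoms

`longmed` quantifies how much of the effect of REM sleep behavior
disorder (RBD) on activities of daily living (ADL) in Parkinson's
disease travels through depression and through cognition, and how that
mediated share evolves over the disease course. It is aimed at
biostatisticians and epidemiologists working with repeated-measures
rating-scale panels: RBDSQ (exposure, 0–13), GDS-15 (depression, 0–15),
MoCA (cognition, 0–30), MDS-UPDRS Part II (ADL, 0–52), observed at a
baseline visit plus eight annual follow-ups, with visit *k* mapped to
normalized study time *t = k/8*.

Two estimators form the core:

* **Bayesian dynamic mediation** (per mediator). A two-equation
  time-varying-coefficient model,

  *M<sub>ik</sub> = a₀(t) + α(t)X<sub>ik</sub> + γ′C<sub>i</sub> +
  u<sup>M</sup><sub>i</sub> + ε*,  
  *Y<sub>ik</sub> = b₀(t) + β(t)M<sub>ik</sub> + τ(t)X<sub>ik</sub> +
  γ′C<sub>i</sub> + u<sup>Y</sup><sub>i</sub> + ε′*,

  with all coefficient curves on a B-spline basis of *t*, subject
  random intercepts, and a conjugate blocked Gibbs sampler. The
  indirect-effect curve IE(*t*) = α(*t*)·β(*t*) is summarized with
  posterior mean, SD and equal-tailed 95% credible bands.

* **Mediational g-formula** (both mediators jointly). Parametric
  component models per visit, Monte Carlo counterfactual simulation
  under sustained high-vs-low exposure regimes with common random
  numbers, a two-way decomposition TE = DE + IE<sub>joint</sub> + ξ
  (exact by construction; ξ is the residual against an unmediated
  anchor model), a path-specific decomposition of IE<sub>joint</sub>
  into per-mediator contributions, subject-level bootstrap intervals,
  and an exact enumeration oracle for discrete toys.

Supporting modules provide a validated long-format cohort container
with scale-range checks and clinical cut-offs, a seeded synthetic
cohort generator with known mediation structure (the package's study
conditions: 337 subjects, 9 visits), descriptive baseline tables and
correlation matrices, and a Monte Carlo post-hoc power analysis for
indirect effects.

## Worked example

```r
library(longmed)

panel <- simulate_cohort(dgp_config(), seed = 20260320)  # 337 x 9 panel
fit <- fit_dynamic_mediation(
  panel, dynmed_spec("gds15", n_iter = 5000, n_warmup = 2000,
                     n_chains = 2, seed = 20260320))
indirect_effect_curve(fit, c(0.25, 0.50, 0.75))
```

```
     t ie_mean  ie_sd ci_low ci_high
  0.25  0.0246 0.0068 0.0124  0.0395
  0.50  0.0486 0.0094 0.0314  0.0681
  0.75  0.0826 0.0120 0.0599  0.1073
```

The standardized indirect effect of RBD on ADL through depression is
positive at every reporting timepoint and more than doubles between
t = 0.25 and t = 0.75: the mediated share of the harm grows as the
disease progresses. The credible bands exclude zero throughout.

Joint mediation through both mediators, with bootstrap intervals:

```r
spec <- gformula_spec(n_mc = 20000, n_boot = 200, seed = 20260320)
gformula_bootstrap(panel, spec, n_mc_boot = 5000)
```

```
g-formula decomposition with subject bootstrap (200 replicates)
 component estimate ci_low ci_high
        te    5.230  3.772   6.882
        de    2.005  0.959   3.006
  ie_joint    1.573  1.187   1.990
        xi    1.653  0.680   2.888
  ie_gds15    0.854  0.600   1.182
   ie_moca    0.719  0.458   1.033
```

Under a sustained 90th-vs-10th-percentile RBDSQ contrast, final-visit
ADL limitation rises by about 5.2 points in total; roughly 1.6 points
flow through the two mediators jointly, with depression (0.85) a larger
conduit than cognition (0.72). ξ reports the gap between the unmediated
anchor estimate and the mediational decomposition (here inflated by
score clipping in the generator; see the vignette), and
te = de + ie_joint + xi holds exactly.

## The analysis workflow

The `analysis/` directory is a numbered, re-runnable pipeline over the
package functions; each stage prints what it found and writes its
tables under `results/`:

| stage | script | output |
|---|---|---|
| 1 | `analysis/01_simulate.R` | `results/cohort.csv`, true effect curves |
| 2 | `analysis/02_descriptives.R` | baseline ADL table, correlation matrix |
| 3 | `analysis/03_dynamic_mediation.R` | IE(t) curves + convergence reports |
| 4 | `analysis/04_gformula.R` | decomposition table with bootstrap CIs |
| 5 | `analysis/05_power.R` | power per indirect effect |

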