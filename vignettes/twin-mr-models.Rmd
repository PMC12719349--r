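---
title: "Causal twin models with polygenic-score instruments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal twin models with polygenic-score instruments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmr)
```

## The models

`twinmr` implements three bivariate twin models for causal inference
between an exposure (Trait 1) and an outcome (Trait 2), as exact
covariance structures for monozygotic (MZ) and dizygotic (DZ) twin pairs.

Per twin, the latent traits obey the structural equations

$$
T_1' = g_2 T_2' + b_1 \mathrm{PS}_1 + A_1 + C_1 + E_1, \qquad
T_2' = g_1 T_1' + b_2 \mathrm{PS}_1 + b_3 \mathrm{PS}_2 + A_2 + C_2 + E_2,
$$

where $g_1$ and $g_2$ are the causal paths between the traits,
$\mathrm{PS}_1$ and $\mathrm{PS}_2$ are polygenic scores instrumenting the
exposure and the outcome, and each trait carries additive-genetic ($A$),
shared-environment ($C$) and unshared-environment ($E$) residual factors.
The factor pairs may covary across traits (components `covA`, `covC`,
`covE`, reported as the correlations $r_a$, $r_c$, $r_e$): these are the
confounding channels.  Cross-twin covariances follow the classical twin
rules — $A$ terms weighted 1 in MZ and 0.5 in DZ pairs, $C$ terms 1 in
both, $E$ terms 0.  Polygenic scores are additive-genetic quantities, so
their variances and their mutual correlation $r_f$ follow the genetic
rule; within a person the two scores correlate $r_f$, which (together with
causal effects on the exposure) is the indirect-pleiotropy channel
$r_f b_1$, $r_f b_3$.

The three models are nested restrictions of this system:

* **DoC** (`model_spec("DoC")`): no instruments.  Free: $g_1$, the per-trait
  A/C/E components, `covA`, `covC`.  Identification requires $r_e = 0$ and
  $g_2 = 0$.
* **MR-DoC** (`model_spec("MR-DoC")`): one instrument.  Adds $b_1$ and the
  *direct* horizontal-pleiotropy path $b_2$; still fixes $r_e = 0$,
  $g_2 = 0$.
* **MR-DoC2** (`model_spec("MR-DoC2")`): two instruments, bidirectional
  causation, free $r_e$ (`covE`) and $r_f$; fixes $b_2 = 0$.

Estimation is in *variance components*: the components are unbounded (they
may go negative at the solution), and correlations are derived afterwards
with `component_correlations()`.  An implied covariance matrix that is not
positive definite during optimization is rejected through an infinite
discrepancy sentinel rather than by bounding the components.

### The reduced form and its admissibility gate

The feedback loop is solved by inverting the $2 \times 2$ causal
coefficient matrix, which exists iff $|g_1 g_2| < 1$; parameter sets
violating this are rejected at construction.  Means are fixed at zero
throughout: exact-moment data are zero-mean and means carry no information
about the covariance structure.

### Variable ordering and the MZ polygenic-score degeneracy

The observed vector stacks twin 1 then twin 2, each twin ordered
(PS1, PS2, T1, T2) restricted to the model's variables; the ordering is
asserted in the test suite.  MZ twins carry *identical* polygenic scores,
so the full MZ matrix of an instrumented model is singular (positive
semidefinite, with each PGS duplicated across twins).
`expected_covariance()` returns this full matrix — it is the population
covariance of the stacked vector — while the likelihood is evaluated on
the non-degenerate MZ vector in which each PGS enters once.  The DZ group
keeps all variables.

## Maximum-likelihood fitting and power

`ml_discrepancy()` is the standard multigroup normal-theory fit function
on the $-2\ln L$ difference scale, with twin *pairs* as the sampling unit
($n_\mathrm{MZ} = n_\mathrm{DZ} = 1000$ pairs by default, the scale used
throughout the simulation studies).  Fitting is done directly to
covariance matrices: with exact-moment data this is likelihood-equivalent
to fitting raw data (a raw-data path, `exact_sample()` plus
`sample_covariance()`, exists and is used as a cross-check in the tests).

`fit_model()` minimizes the discrepancy with a quasi-Newton optimizer
(`nlminb`, numerically evaluated derivatives, relative tolerance
$10^{-12}$) and up to five seeded jittered restarts, alternating polish
passes near the best solution with fresh jitters of the starting values.
A fit is `converged-clean` — an estimation finishing without warnings —
when the solution is admissible (finite discrepancy, positive-definite
implied matrices) and the maximum absolute numerical gradient is below
$10^{-3} \max(1, |F|)$.  On the $-2\ln L$ scale of 2000 pairs that is
roughly $5\times 10^{-7}$ per observation, about the floor achievable with
finite-difference derivatives; the optimizer's own return code is
advisory only, since it reports false convergence when started exactly at
the optimum (which exact-data fits do by design).

Starting values are the generating values (with constrained entries
overwritten), which makes exact-data fits deterministic and nearly
noiseless.  For fits to correlation-scaled matrices the start is obtained
in closed form: the model family is closed under a diagonal rescaling of
the observed variables, and `rescale_parameters()` maps the generating
values to the standardized scale exactly.

For a nested null hypothesis (here, $g_1 = 0$), `ncp_for_test()` fits the
model unconstrained and constrained to *exact* data; the $-2\ln L$
difference is then the non-centrality parameter (NCP) of the
likelihood-ratio test, and `power_from_ncp()` converts it to power through
the noncentral chi-square tail.  Exact data make this noiseless: the NCP
is proportional to the pair counts, and tiny negative differences (above
$-10^{-6}$) are clipped to zero.

## The synthetic-data stage

There are no external data: every experiment generates its inputs.

* `build_grid()` materializes the three factorial designs as deterministic
  lexicographic enumerations with stable integer cell ids (3^7 = 2187,
  3^9 = 19683 and 3^12 = 531441 cells).  Path factors take levels
  $\sqrt{0.025}$–$\sqrt{0.04}$ (instruments) and $\sqrt{0.02}$–$\sqrt{0.04}$
  (causal paths), so that the *variance* contributed is the round number;
  correlations take 0.1/0.2/0.3 ($r_a$, $r_c$, $r_e$) and 0.1/0.2/0.5
  ($r_f$); $a^2 \in \{0.3, 0.4, 0.5\}$ and $c^2 \in \{0.1, 0.2, 0.3\}$ with
  $e^2 = 1 - a^2 - c^2$ per trait, so each trait's residual variance is 1.
  Grids are held as data frames of factor levels; `cell_parameters()`
  materializes one generating parameter set per cell on demand, converting
  the correlation factors to covariance components.  PGS variances are 1
  in all generating cells, making $b_1$, $b_3$ directly comparable to the
  other standardized paths.
* `add_measurement_error()` replaces the traits by unreliable indicators:
  loading $\sqrt{\mathrm{rel}}$, twin-specific residual variance
  $1 - \mathrm{rel}$ (not transmissible: no cross-twin error covariance).
  The distortion is applied at the covariance level — the distorted matrix
  is then *used as data* — which is exact and equivalent to augmenting the
  generating model.  The study settings are reliability 0.9 for the
  exposure and 0.7 for the outcome.
* `inject_re()` sets `covE` to $r_e \sqrt{e_x^2 e_y^2}$ in the generating
  parameters (study settings $r_e = \pm 0.3$), while DoC and MR-DoC are
  still *fitted* with $r_e = 0$: the misspecification of interest.
* `marginalize()` extracts a nested model's observed block from
  MR-DoC2-generated covariances for the cross-model experiments.
* `exact_sample()` draws seeded Gaussian samples whose sample moments
  equal the target exactly (center, whiten by the sample covariance's
  Cholesky inverse, recolor), with the $n - 1$ covariance denominator.

What the generator deliberately does not emulate: non-Gaussian phenotypes,
missing data, ascertainment, sampling variability (exact moments remove
it), and real polygenic-score construction.  Passing tests therefore
demonstrate *asymptotic, structural* properties — biases that survive at
the population level — not finite-sample behavior of real twin registries.

## The experiments

`run_bias_experiment()` crosses a generating model, a fitted model and a
distortion scenario over a design grid, records `estimate − true` for
every free parameter (plus derived correlations), and
`summarize_bias()` pools cells within a scenario (one mean per parameter,
non-converged cells excluded and counted).  The sign convention is
estimate minus generating value, so overestimation is positive.

`run_power_experiment()` computes each cell's exact covariances,
standardizes them with `cov2cor` scaling, tests $g_1 = 0$ (1 df,
$\alpha = 0.05$), and `regress_ncp()` fits an ordinary least-squares
regression of the NCP on the design factors — main effects only, matching
a one-coefficient-per-parameter display; predictors are z-scored for
display, which leaves $R^2$ unchanged.  The optional 2-df joint test of
both causal paths is available through `ncp_for_test()` with two
constraints but is not part of the headline experiments.

### Problem sizes

The package's default experiment sizes are seeded uniform subsamples of
300 cells for Designs 1–2 and 500 cells for Design 3 (full-grid runs are
available behind a flag in the CLI); bias sign checks in the test suite
use 30–40-cell subsamples, where the pooled means are already stable.
Monte-Carlo validation of the covariance algebra uses $10^6$ simulated
pairs per checked cell.

## Numerical and design choices

* **Degenerate inputs.** Non-positive-definite *data* matrices are errors;
  non-positive-definite *implied* matrices are step rejections.  Undefined
  derived correlations (non-positive component products, possible with
  unbounded estimates) are returned as `NA`, never silently propagated as
  `NaN`.
* **Ties and reproducibility.** Grid enumeration is lexicographic in the
  design's factor order (first factor slowest), so cell ids are stable
  across runs and subsamples preserve them; all stochastic steps (subsample
  draws, restart jitters, exact samples) are seeded and restore the
  caller's RNG state.
* **re at generation vs estimation.** The structural path fixes of a model
  ($b$ paths, $g_2$, $r_f$) are validated when generating covariances, but
  `covE` is deliberately exempt: fixing $r_e = 0$ is an estimation-time
  identification constraint, and the misspecification experiments generate
  DoC/MR-DoC-structured data with $r_e \neq 0$ on purpose.
* **PGS cross-twin rule.** Polygenic scores are treated as additive-genetic
  quantities (cross-twin weight 1 MZ / 0.5 DZ for variances and the $r_f$
  cross-covariance alike), and are uncorrelated with the residual A/C/E
  factors: instrument effects run only through $b_1$, $b_2$, $b_3$.

## Known limitations and expected behavior under distortion

Two structural results are worth stating because they govern what the
experiments can show.

First, the reliability distortion maps the covariance structure *exactly*
onto another member of the MR-DoC2 family: with reliabilities
$(\rho_1, \rho_2)$ the fitted causal paths converge to
$g_1 \sqrt{\rho_2 / \rho_1}$ and $g_2 \sqrt{\rho_1 / \rho_2}$, the
instrument paths to $\sqrt{\rho_1}\, b_1$ and $\sqrt{\rho_2}\, b_3$, and
the E components absorb the twin-specific error variance.  MR-DoC2's
causal estimates are therefore *nearly* — not exactly — unaffected by
measurement error: with 0.9/0.7 reliabilities the asymptotic distortion of
$g_1$ is about $-12\%$ of its value (around $-0.02$ at the design's
levels), far smaller than the attenuation in DoC and MR-DoC but nonzero.
The test suite asserts the strict $\pm 0.01$ band and documents the
failure rather than widening it.

Second, in DoC and MR-DoC the $g_1 = 0$ null forces the within-person and
MZ cross-twin cross-trait covariances to be equal, while the generated
data differ by exactly $g_1 e_x^2$: the causal-test NCP is therefore
necessarily a product of $g_1^2$, the exposure's unshared-environment
variance, and a weighting term.  With $e^2 = 1 - a^2 - c^2$ varying across
the factorial cells, a main-effects regression of the NCP on the factors
has a hard additive ceiling around $R^2 \approx 0.90$ for Design 1 (the
saturated per-factor fit), and the package reports $R^2 \approx 0.89$
there — the interaction (product) share is real, not noise.  The same
product structure with $b_1$, $r_f$ and $g_1$ active yields
$R^2 \approx 0.96$ for Design 3.  This also explains why the E variance
acts as a latent instrument in these models: all information about $g_1$
flows through the unshared-environment channel once $r_e$ is fixed to
zero.  A corollary, verified to machine precision in the tests, is that
the MR-DoC causal-test NCP is *exactly* invariant in the instrument
strength $b_1$ (and equals the corresponding DoC NCP): the observed
instrument contributes nothing to the power to reject $g_1 = 0$ when
$r_e$ is fixed, so MR-DoC does not require a strong instrument — but any
regression estimate of $b_1$'s contribution on a finite subsample is pure
noise around zero.

## A worked example

```{r example, eval = FALSE}
spec <- model_spec("DoC")
theta <- correlations_to_covariances(
  parameter_set(g1 = sqrt(0.03), aX2 = 0.4, cX2 = 0.2, eX2 = 0.4,
                aY2 = 0.4, cY2 = 0.2, eY2 = 0.4),
  ra = 0.2, rc = 0.2)
S_mz <- expected_covariance(spec, theta, "MZ")
S_dz <- expected_covariance(spec, theta, "DZ")
res <- ncp_for_test(spec, S_mz, S_dz, start = theta,
                    null_constraints = list(g1 = 0))
res$ncp                      # 30.75
power_from_ncp(res$ncp)      # 0.9998
```

The same cell under reliability 0.9/0.7 shows the attenuation bias:

```{r example2, eval = FALSE}
S_mz_obs <- add_measurement_error(S_mz, 0.9, 0.7)
S_dz_obs <- add_measurement_error(S_dz, 0.9, 0.7)
f <- fit_model(spec, S_mz_obs, S_dz_obs, start = theta)
f$estimates$g1 - theta$g1    # about -0.06: the causal path is attenuated
```
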