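---
title: "Weighted Bayesian generalized SEM mediation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Bayesian generalized SEM mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Depressive symptoms in older adults are associated with greater inpatient
healthcare use, but most of that association may flow through intervening
variables — perceived health, chronic disease burden, functional
limitations, health behaviors — rather than directly. Within Andersen's
behavioral model of healthcare utilization (predisposing, enabling and
need factors), **bgsem** estimates how much of the exposure–outcome
association is transmitted through each mediator, using a Bayesian
generalized structural equation model with survey weights.

## The structural system

For subject $i$ with binary exposure $X_i$ (depressive symptoms, CES-D-10
total $\ge 10$), binary outcome $Y_i$ (any inpatient use), mediators
$M_{ki}$ and controls $C_{ji}$:

* **Outcome equation** (Bernoulli-logit):
  $\mathrm{logit}\,P(Y_i = 1) = \alpha_Y + \beta_X X_i + \sum_k \beta_k
  M_{ki} + \sum_j \beta_j C_{ji}$.
* **Binary mediator equations**: $\mathrm{logit}\,P(M_{ki} = 1) =
  \alpha_k + \gamma_k X_i$.
* **Ordinal mediator equations** (cumulative logit, latent-shift form):
  $\mathrm{logit}\,P(M_{ki} \le m) = \alpha_{km} - \gamma_k X_i$ with
  strictly increasing thresholds $\alpha_{km}$.

Mediator equations contain only the exposure; a mediator never appears in
another mediator's equation. No parameter is shared between equations, so
the joint posterior factorizes over sub-models and each can be sampled
independently — an exact property of this system, not an approximation.

**Sign convention.** The latent-shift form above means a *positive*
$\gamma_k$ moves mass toward *higher* categories. The alternative
convention (with $+\gamma_k$ on the cumulative-lower logit) flips the
sign. We adopt latent shift because it is the convention of the common
ordinal samplers and it makes the reported path signs coherent: a negative
exposure-to-health-status coefficient then means the exposed group shifts
toward poorer self-rated health, which is the direction required for the
published positive indirect associations. The printed equation form and
the printed coefficient signs cannot both be taken literally; we follow
the signs.

**Ordinal variables in the outcome equation.** Each ordinal mediator (and
by default each multi-level control) enters the outcome equation as its
0-based integer score, giving one coefficient per variable. A single
published coefficient per multi-level variable implies exactly this
linear-score coding; full dummy expansion for controls is available via
`model_spec(..., control_coding = "dummy")`. A monotonic-effects
treatment of ordinal predictors is out of scope.

**Survey weights.** Weights are normalized to mean 1 at load
(`normalize_weights()`, sum = $n$, ratios preserved) and multiply every
observation's log-likelihood contribution in *every* sub-model
(pseudo-likelihood). Where the weights enter is a modeling decision the
source analysis leaves open; weighting all sub-models is the coherent
choice for a jointly weighted system and is what `build_model()`
documents. No design-based variance correction is attempted.

## Priors

* `prior_config("default")`: Cauchy(0, 2.5) on every regression
  coefficient; Student-t(3, 0, 2.5) on intercepts and ordinal thresholds.
* `prior_config("diffuse")` (the sensitivity preset): flat coefficient
  priors, bounded at $\pm 1000$ so the posterior remains proper, and
  Student-t(1, 0, 1000) on intercepts and thresholds.

The Cauchy density is evaluated directly. A scale-mixture representation
is the usual remedy for heavy-tailed priors under Gibbs-style samplers;
under gradient-based HMC the Cauchy log-density is smooth everywhere and
sampling it directly is simpler and adequate, so no auxiliary scale
variables are introduced. With a zero-row dataset the posterior *is* the
prior, and `fit()` then returns i.i.d. prior draws (ordinal thresholds as
the order statistics of the threshold prior) rather than running a chain.

## Sampling

`fit()` runs a static Hamiltonian Monte Carlo sampler written for this
package (Rcpp):

* **Warmup** (default half of `iter`): dual-averaging step-size
  adaptation toward `target_accept` (default 0.9); a diagonal metric is
  estimated from the draws of the first warmup phase and installed at
  mid-warmup, after which step-size adaptation restarts.
* **Trajectories**: leapfrog length is drawn uniformly so the total
  integration time is approximately uniform on $(0, 2\pi]$ in
  metric-scaled units (the range adapts to the step size), with a
  $\pm$10% step-size jitter; both randomizations suppress the periodic
  return behavior of near-Gaussian targets.
* **Exact reductions**: mediator sub-models depend on the data only
  through a handful of (exposure, response) cells, so their weighted
  likelihoods are collapsed to sufficient statistics before sampling;
  all designs are centered at their weighted means during sampling
  (intercept and threshold priors act on the centered scale, as in the
  common regression samplers) and draws are mapped back to the natural
  scale. Ordinal thresholds are sampled on an ordered transform
  (first threshold free, increments log-transformed) with the Jacobian
  included, so ordering holds in every draw by construction.
* **Determinism**: all chain seeds derive from `mcmc_config(seed = )`;
  identical input gives identical draws. Iterations with non-finite
  density or energy error above 1000 are rejected and counted; a chain
  with more than 10% such transitions is flagged in `fit()$warnings`.

Two configurations are used throughout: the study-scale profile
(4 chains × 10,000 iterations, 5,000 warmup) mirroring the original
computational settings, and the desk-scale profile (2 × 1,500, 750
warmup) used by the package's own simulation studies, the analysis
scripts and the test suite. Problem sizes in the tests (n = 4,000
cohorts, 20 recovery replicates; n = 10,000 for imputation calibration;
n = 5,000 × 500 replicates for the MCAR level check) are the package's
desk-scale choices: large enough for the asymptotics the checks rely on,
small enough to re-run routinely.

## Mediation decomposition

`decompose()` works per posterior draw on the log-odds scale: the
indirect association through mediator $k$ is $\gamma_k \beta_k$, the
total indirect is their sum, and the total association is direct + total
indirect — an identity that holds exactly per draw. Summaries are
posterior means with 95% highest-density intervals (`hdi()`, shortest
contiguous interval over the sorted draws). Combining logit-scale
coefficients across equations ignores the non-collapsibility of the
logit link; this mirrors the published tables and is reported as such.

The proportion mediated is `100 × TI / (TI + direct)` computed from the
posterior *means* — the arithmetic the published percentages follow. A
per-draw-ratio variant (mean and HDI of the per-draw percentage) is also
reported, clearly labeled; it is unstable whenever the per-draw total
crosses zero, which is why the mean-ratio form is primary. Values outside
[0, 100] (inconsistent mediation) are not clamped. Report tables round
half-away-from-zero to two decimals.

Published-table verification (`verify_paper_arithmetic()`) recomputes
every derivable cell from the printed path means. Because the original
tables average per-draw products rather than multiplying averaged paths,
a recomputed product can land one rounding step from the printed cell;
the verifier classifies those as `"rounding"` (three such cells exist in
the comprehensive table: pain, ADL, chronic disease) and anything further
away as `"fail"`.

## Synthetic cohorts

`synthetic_config()` encodes the study conditions as generator defaults:
exposure prevalence 38.24%; control marginals equal to the published
participant-characteristics frequencies; path coefficients equal to the
published posterior means of the chosen specification; mediator
intercepts and thresholds calibrated by root finding so each mediator's
*marginal* distribution matches the published frequencies given its
exposure effect; the outcome intercept calibrated by Monte Carlo (fixed
internal stream, 200,000 draws) to the 19.22% outcome prevalence;
lognormal(0, 0.5) survey weights normalized to mean 1 (the weight
distribution is otherwise unspecified; any positive heteroscedastic
choice exercises the weighted likelihood); and age-driven MAR missingness
at 5% on three need mediators, with the missingness intercept calibrated
to the target marginal rate.

What the generator deliberately does **not** emulate: dependence among
control variables (they are sampled independently), exposure–mediator
interactions, mediator–mediator paths, longitudinal structure, and the
survey's actual design-weight mechanism. Passing recovery tests on these
cohorts therefore demonstrates that the estimation machinery is correct
and calibrated under the model's own assumptions — not that the model is
correct for any real cohort.

Every random source (each control, each mediator, exposure, outcome,
weights, each missingness target) draws from its own substream derived
from the master seed, so adding a variable never perturbs earlier ones.

## Missing data

`littles_mcar_test()` compares each missingness pattern's observed-
variable means with EM estimates of the grand mean and covariance under a
multivariate-normal working model on the numeric codes:
$d^2 = \sum_j n_j(\bar y_j - \hat\mu_j)'\hat\Sigma_j^{-1}(\bar y_j -
\hat\mu_j)$, $df = \sum_j p_j - p$. Treating coded categories as numeric
is an approximation, but pattern means are asymptotically normal under
MCAR regardless of the true distribution, so the test keeps its level
(the suite verifies 3–7% rejection at the 5% level over 500 MCAR
replicates). EM controls: log-likelihood tolerance 1e-6, at most 500
iterations, ridge 1e-8 on the covariance.

`mice_impute()` runs chained equations in schema order (default m = 5
copies, maxit = 10 sweeps; the source analysis states neither, and these
are the field's customary defaults): binary variables by logistic
regression with coefficients drawn from the approximate normal posterior,
ordinal variables by proportional-odds fits with drawn coefficients;
degenerate fits fall back to sampling the observed distribution. Observed
cells are never altered. Whether downstream fitting uses one completed
copy or all m is left to the caller; the analysis scripts fit the first
copy and keep the rest for inspection, since pooling MCMC fits across
copies has no single standard recipe.

`agvif()` computes, per term, GVIF = det(R11)·det(R22)/det(R) on the
correlation matrix of the centered dummy design and reports
aGVIF = GVIF^(1/(2·df)) — comparable across terms of different dimension,
equal to √VIF for one-column terms, and invariant to reference-category
choice.

## Convergence and fit evaluation

`rhat()` is the rank-normalized split R-hat (chains halved, pooled
rank-normal transform, classic potential-scale-reduction). The folded,
tail-sensitive variant is available (`folded = TRUE`) but is not the
default: at the desk-scale draw budget its sampling noise alone can
exceed the 1.01 screening threshold for demonstrably well-mixed chains,
so it cannot certify convergence there; tail behavior is monitored
through the tail ESS instead. `ess()` returns bulk ESS (autocorrelation
series via FFT, Geyer initial positive + monotone sequences, on
rank-normalized split chains) and tail ESS (minimum over the 5% and 95%
quantile indicators).

`waic()` and `loo()` operate on the weighted pointwise log-likelihood
exactly as fitted — each observation's contribution summed over
sub-models (`pointwise_loglik()`). PSIS-LOO fits a generalized Pareto
distribution (Zhang–Stephens profile posterior mean, shape shrunk toward
0.5 with 10 pseudo-observations) to the top 20% of importance weights,
replaces them by GPD quantiles truncated at the raw maximum, and reports
per-observation Pareto k with the conventional 0.7 flag. Information
criteria under pseudo-likelihood weighting are heuristic — they rank
specifications on the same weighted data but have no strict
cross-validation interpretation; model comparison between specifications
with different mediator sets also reflects the differing number of
likelihood terms, which is why the refined system's WAIC/LOOIC are far
below the comprehensive system's.

`sensitivity_run()` fits every (specification × prior) cell with the same
seed and flags path-mean shifts above 0.1 log-odds across priors.
`refine_spec()` automates variable exclusion as "drop a mediator when its
indirect-association 95% HDI covers zero". The original screening also
examined individual path HDIs and effect sizes with judgment; the
automated rule is a documented approximation that agrees on clear-cut
cases.

## Known limitations

* Estimands are associational path products, not counterfactual natural
  direct/indirect effects; no exposure–mediator interactions.
* Logit-scale products are combined across equations without rescaling.
* The MCAR test's normal working model is an approximation for
  categorical codes.
* Survey weights enter as a pseudo-likelihood; credible intervals do not
  account for the sampling design.
* The schema ships the published category sets; item-level derivations
  (e.g., ADL severity cut points) beyond CES-D-10 scoring are the user's
  responsibility, as the underlying questionnaire mappings are not fully
  public.
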