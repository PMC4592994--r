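---
title: "Exact Bayesian ordinal regression with Pólya-Gamma augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Bayesian ordinal regression with Pólya-Gamma augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordpg)
```

## The model

Many phenotypes in plant and animal breeding are scored on an ordered
categorical scale — disease severity from 1 (clean) to 5 (fully infected),
for instance — while most genomic-prediction machinery assumes a Gaussian
response. `ordpg` fits the latent-liability threshold model

$$l_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + b_i + \varepsilon_{ij},
\qquad
y_{ij} = c \iff \gamma_{c-1} < l_{ij} < \gamma_c,$$

where $i$ indexes genotypes (lines), $j$ replicates within genotype,
$\boldsymbol\beta$ are fixed or marker effects, $b_i \sim N(0, \sigma_b^2)$
(jointly $\mathbf b \sim N(0, \mathbf G\sigma_b^2)$ with a genomic
relationship matrix $\mathbf G$) is an optional polygenic effect, and the
$C-1$ strictly increasing thresholds $\gamma_c$ cut the liability axis into
$C$ ordered categories. The outer cells extend to $\pm\infty$; the
thresholds absorb any intercept, which is why a constant column in the
design is rejected at validation.

With standard-normal errors this is the classic Bayesian probit ordinal
model (BPOR), whose Gibbs sampler has been routine since the early 1990s.
With standard-logistic errors — the Bayesian logistic ordinal regression,
BLOR — the coefficient conditional is not conjugate. The package restores
conjugacy exactly, not approximately, by augmenting each observation with a
Pólya-Gamma variable

$$\omega_{ij} \mid \text{ELSE} \sim \mathrm{PG}\!\left(2,\;
-l_{ij} + \mathbf{x}_{ij}'\boldsymbol\beta + b_i\right),$$

after which every full conditional is truncated-normal, multivariate
normal, scaled inverse chi-square, or uniform. The PG density is symmetric
in its tilt, so the sign of the argument is immaterial; we keep the form
above because it is the natural residual. Setting every $\omega_{ij} = 1$
(the `link = "probit"` option) reduces the sweep to the probit sampler
*exactly*: the same code path, the same draws under a shared seed, which is
tested draw-for-draw.

One Gibbs sweep updates, in order:

1. liabilities $l_{ij} \sim N(\mathbf{x}_{ij}'\boldsymbol\beta + b_i,
   1/\omega_{ij})$ truncated to $(\gamma_{y-1}, \gamma_y)$;
2. augmentation values $\omega_{ij} \sim \mathrm{PG}(2, \cdot)$ (logit
   only);
3. coefficients $\boldsymbol\beta \sim N_p(\tilde\beta_0, \tilde\Sigma_0)$
   with $\tilde\Sigma_0 = (\Sigma_0^{-1}\sigma_\beta^{-2} +
   \mathbf X'D_\omega \mathbf X)^{-1}$;
4. polygenic effects $\mathbf b$ from their $I$-variate normal conditional
   (skipped, with $\mathbf b \equiv 0$, when no relationship matrix is
   supplied);
5. $\sigma_b^2 \sim \chi^{-2}(\nu_b + I, \cdot)$;
6. thresholds, each uniform on the interval pinched by the extreme
   liabilities of the adjacent categories, the neighboring thresholds, and
   the prior bounds $(\gamma_{\min}, \gamma_{\max})$;
7. $\sigma_\beta^2 \sim \chi^{-2}(\nu_\beta + p, \cdot)$ (skipped when the
   prior fixes it).

The printed normalizer of the liability conditional is treated as the
correctly normalized truncated normal with variance $1/\omega_{ij}$ — the
only reading under which the augmented joint admits a valid Gibbs sweep.

### Thresholds versus liability bounds

Two distinct roles are often conflated. For the *liability partition* the
sentinels are $\gamma_0 \equiv -\infty$, $\gamma_C \equiv +\infty$: an
observation in the bottom category pushes its liability into an unbounded
left tail. The *prior bounds* $\gamma_{\min} < \gamma_{\max}$ apply only to
the threshold draws of step 6 (the order-statistics uniform prior). The
real-data profile uses $\pm 1000$ (effectively flat); the simulation
profile uses $\pm 4$.

Thresholds are swept in increasing order, each conditional using the
freshest lower neighbor, so a run is a deterministic function of the seed.
Every category 1..C must be observed: an empty category makes its
threshold interval unbounded, and validation rejects the data set before
any sampling starts.

## Sampling primitives

* **Pólya-Gamma.** PG$(1, c)$ uses Devroye's exact alternating-series
  rejection sampler; PG$(b, c)$ for integer $b$ is the $b$-fold sum
  (infinite divisibility). Exactness matters: the selling point of the
  logit sampler is that it is not a moment-matched approximation, so
  approximate PG samplers are deliberately out of scope, and non-integer
  shapes (never needed by the model, which uses $b = 2$) are rejected
  rather than approximated.
* **Truncated normal.** Intervals near the mode use normal or
  tilted-uniform rejection; one-sided and two-sided intervals deep in a
  tail switch to shifted-exponential proposals. Liabilities of rare
  categories land many SDs out, so the tail route is exercised routinely;
  a dedicated test draws from $(8, 9)$ on a standard normal and checks
  strict containment.
* **Scaled inverse chi-square** is $\nu s / \chi^2_\nu$, used by both
  variance conditionals.

All randomness flows through R's own RNG (also from the C++ code), so
`set.seed()` makes entire chains bit-reproducible. Replicate- and
split-level sub-seeds are derived deterministically from a master seed via
`derive_seed()`, keeping replicated studies independent of execution
order.

### High-dimensional marker models

When all markers enter $\mathbf X$ with the shrinkage prior
$\boldsymbol\beta \sim N(0, \mathbf I\sigma_\beta^2)$, the model is a
threshold Bayesian ridge regression; the conditional posterior mean is the
classic ridge estimator $(\mathbf X'D_\omega\mathbf X +
\mathbf I\sigma_\beta^{-2})^{-1}\mathbf X'D_\omega \mathbf l$ with the
liabilities as pseudo-response. Factorizing a $p \times p$ precision with
tens of thousands of markers is infeasible, so for $p > 2n$ the draw
switches automatically to an $n$-dimensional auxiliary-variable algorithm
(the Bhattacharya–Chakraborty–Mallick identity) whose output distribution
is *identical* to the direct draw; a shared-prior two-moment test holds the
two routes against the closed form. Marker codes are not centered
automatically — centering is the caller's choice and the validation only
requires completeness (no imputation is performed here; filter and impute
upstream).

## Priors and defaults

| Parameter | Default | Role |
|---|---|---|
| $\beta_0, \Sigma_0$ | $0$, $10000\,\mathbf I$ | weakly informative normal prior on $\boldsymbol\beta$ |
| $\nu_\beta, S_\beta$ | 3, 0.001 | scaled inv-$\chi^2$ on $\sigma_\beta^2$ |
| $\nu_b, S_b$ | 5, 1 | scaled inv-$\chi^2$ on $\sigma_b^2$ |
| $\gamma_{\min}, \gamma_{\max}$ | $-1000$, $1000$ | threshold prior bounds |
| chain | 60,000 / 20,000 | real-data profile, no thinning |

The defaults are the weakly informative real-data settings. The polygenic
hyperparameters $\nu_b = 5$, $S_b = 1$ are this package's choice (a mild
prior centered on a liability-scale variance of order one, the usual
practice in threshold animal models); nothing in the replicated simulation
designs uses them, since those designs carry no polygenic term.
`sim_prior()` is the replicated-study configuration: $\Sigma_0 = 10000\,
\mathbf I_3$ with $\sigma_\beta^2$ fixed at 1 (the simulation designs
state no hyperprior for it), bounds $\pm 4$. Chains are never thinned:
subsampling MCMC output only loses precision for means, variances and
quantiles.

An improper flat prior on $\boldsymbol\beta$ is available
(`improper_beta`): the $\Sigma_0$ terms vanish from the coefficient
update, $\sigma_\beta^2$ loses its role and is held fixed, and a
rank-deficient $\mathbf X'D_\omega\mathbf X$ then raises a singularity
error instead of being silently regularized.

Initialization (the published description is silent here): thresholds at
the standard-normal quantiles of the empirical cumulative category
frequencies, clipped inside the prior bounds and nudged apart if ties
occur; $\boldsymbol\beta = 0$; $\mathbf b = 0$; $\sigma_b^2 = S_b$;
$\sigma_\beta^2 = 1$; liabilities at their category midpoints ($\mp 0.5$
beyond the boundary threshold for the end categories); $\omega = 1$. All
starting points lie in the support; with the chain lengths used, burn-in
comfortably forgets them.

## The simulation designs

`sim_spec()` encodes the two replicated designs used for benchmarking.
Both draw covariates $\mathbf x_i \sim U[-0.1, 0.1]^3$ for $I = 40$
genotypes, set $\boldsymbol\beta = (-6, -5, 7)$ and cut liabilities at the
symmetric standard-normal quintile thresholds
$(-0.8416, -0.2533, 0.2533, 0.8416)$ into five categories. Study 1 uses
standard-logistic errors with $n_i \in \{5, 10, 20, 40\}$ replicates per
genotype; study 2 fixes $n_i = 40$ and replaces a uniformly chosen
`po` percent of the 1600 residuals with unscaled Student-$t_4$ draws
(5–30%), the classical heavy-tail contamination model.

Two deliberate reading choices, both documented because the source text is
internally inconsistent: the sign of $\beta_2$ is taken as $-5$ (the
tabulated true value; the running text prints $+5$), and the thresholds
are taken as the monotone quintile cutpoints (the running text prints two
of them with impossible signs). Covariates are redrawn each replicate by
default — the alternative single-shared-design reading is available via
`shared_x = TRUE` — so across-replicate SDs reflect full sampling
variability; exact SD comparisons against published tables inherit this
ambiguity. The $t_4$ contamination is used unscaled, as specified. One
further numerical subtlety: the logistic distribution has *heavier*
central-to-moderate tails than $t_4$ ($P(|L| > 4) = 0.036$ versus
$0.016$); the polynomial $t_4$ tail only dominates beyond roughly
$\pm 7$, so tail-dominance checks in the tests sit at $\pm 8$.

`run_replication_study()` generates the replicates, fits any subset of
{BLOR, BLOR\*, MLLOR, MLLOR\*, BPOR}, and reports across-replicate means
and SDs per parameter. Bayesian point estimates are posterior means; the
starred methods multiply probit estimates by $k = 1.75$ (the
Kullback–Leibler-optimal logit/probit scaling; 1.702 is also accepted). A
replicate on which a method fails is excluded with a recorded message and
count, never silently.

What the generator emulates — and does not. It reproduces the replicated
benchmark conditions exactly: small bounded covariate effects, balanced
replication within genotype, clean or $t_4$-contaminated residuals. It has
no markers, no linkage disequilibrium structure, no polygenic term, no
genotype-by-environment interaction and no missingness, so passing the
recovery tests demonstrates correctness of the samplers and estimators
under the stated conditions, not predictive performance on real breeding
data.

## Baselines and metrics

* `fit_cumulative_link()` is a bespoke damped-Newton MLE of the
  cumulative-link model with thresholds reparameterized as log-increments
  (monotone by construction), analytic gradient and finite-difference
  Hessian. Convergence uses a scale-aware gradient criterion
  ($\|\nabla\| < 10^{-8}\max(1, |\ell|)$), since an absolute cutoff is
  unattainable at large $n$ with a finite-difference Hessian. It matches
  `MASS::polr` (the reference general-purpose fitter, which shares this
  parameterization) to four significant figures in log-likelihood on
  randomized data sets — `polr` serves as oracle only, never as the
  implementation.
* `category_probabilities()` and `posterior_category_probabilities()`
  compute $\pi_c = F(\gamma_c - \eta) - F(\gamma_{c-1} - \eta)$ per draw;
  credible sets are equal-tailed posterior quantiles, at 95% by default
  (the conventional level; configurable). Reported per-category summaries
  average over observations.
* `brier_score()` is the multi-category Brier score divided by 2, mapping
  its natural $[0, 2]$ range onto $[0, 1]$; lower is better.
* `dic()` uses the classic plug-in form $2\bar D - D(\bar\theta)$ with
  $\bar\theta$ the joint posterior mean of $(\boldsymbol\beta, \mathbf b,
  \boldsymbol\gamma)$; probabilities below a configurable floor
  ($10^{-12}$) are clamped with a warning before logs are taken.
* `cross_validate()` runs ten independent uniform random 90/10
  observation-level splits (no stratification), scores held-out halved
  Brier per split from posterior-mean parameters — so exact fits and
  $k$-scaled approximations are treated identically — and reports mean,
  min and max. Posterior-predictive averaging over draws is available
  behind `average_draws = TRUE`. A training split missing a category is
  redrawn (the model cannot be fit without it); a test fold missing one
  only warns.

## Worked example

```{r example, eval = FALSE}
spec <- sim_spec(study = 1, n_i = 40, seed = 7)
sim <- simulate_ordinal(spec, rep = 1)

fit <- blor(sim, y ~ x1 + x2 + x3, prior = sim_prior(),
            chain = blor_chain(profile = "simulation", seed = 11))
tidy(fit)
glance(fit)          # DIC and training Brier score
autoplot(fit)        # trace plots
predict(fit)[1:3, ]  # per-category probabilities

# probit fit and its k-scaled logit approximation
bpor <- blor(sim, y ~ x1 + x2 + x3, prior = sim_prior(),
             chain = blor_chain(profile = "simulation", link = "probit",
                                seed = 11))
blor_star <- scale_probit_to_logit(bpor, k = 1.75)
```

## Problem sizes and numerical choices

The replicated recovery runs in the test-suite and the acceptance script
use the full published design where it is cheap (50 replicates of
20,000-sweep chains at $n = 200$; the complete 50-replicate MLE studies)
and shortened chains of 4,000 sweeps / 2,000 burn-in for the $n = 1600$
designs, with 20-replicate runs for the contamination-trend and
consistency-pattern properties. These sizes are the package's choice of
desk-scale reproduction; the across-replicate standard errors quoted in
the tests are computed from the published SDs at the replicate counts
actually run. Statistical tolerances are three standard errors of the
relevant Monte-Carlo mean throughout.

Degenerate inputs are rejected rather than repaired: empty categories,
constant design columns, incomplete marker matrices, non-SPD relationship
matrices, inverted truncation intervals, non-positive PG shapes, and
threshold intervals that collapse during sampling (which would indicate an
inconsistent state) all raise typed errors.

## Known limitations

* No genotype-by-environment interaction terms; an environment label in a
  phenotype file is carried but ignored by the model.
* No variable-selection priors (BayesB/C-style sparsity) and no multi-trait
  models.
* Convergence tooling is limited to trace export/plots; run-length choices
  follow the fixed no-thinning profiles.
* The MLE reports point estimates only (the replicated studies summarize
  across replicates); no Wald standard errors.
* Cross-validation refits without the polygenic term; genomic
  cross-validation with line-level blocking is out of scope.
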