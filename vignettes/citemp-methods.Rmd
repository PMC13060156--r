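---
title: "Models and methods for temperature-sensitive CI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for temperature-sensitive CI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citemp)
```

# The scientific problem

Cytoplasmic incompatibility (CI) kills embryos fathered by
*Wolbachia*-bearing males unless the mother carries a compatible
*Wolbachia*. CI strength — the share of embryos killed — varies with the
male's rearing temperature, and candidate explanations range from
symbiont density in the testes to transcription of the phage-encoded
toxin gene *cifB*. Measuring this requires a chain of analyses on very
different data types: bounded hatch counts with excess zeros,
coarsely-gridded development times, qPCR/ddPCR relative quantification,
and cross-strain comparisons that must respect the strains' shared
ancestry. `citemp` implements that chain end to end.

# The hatch-count model

Each egg-lay replicate contributes hatched eggs $y_i$ out of $n_i$. The
model is a zero-inflated binomial GLMM with a logit link:

$$
P(y_i) \;=\; \pi\,\mathbf 1\{y_i = 0\} \;+\;
(1-\pi)\int \mathrm{Bin}\!\big(y_i;\, n_i,\,
\mathrm{logit}^{-1}(\eta_{c(i)} + u)\big)\,
\varphi(u; 0, \sigma^2)\, du .
$$

* $\eta_{c}$ — one logit-scale mean per strain × temperature × cross
  cell. We parameterize the fixed effects as **saturated cell means**
  rather than treatment contrasts: for a full-interaction model the two
  are equivalent, and cell means make estimated marginal means and all
  odds-ratio contrasts exact linear reads of the coefficient vector.
* $\sigma$ — SD of an observation-level random effect (one Gaussian
  deviate per replicate) that absorbs overdispersion relative to the
  binomial. Unit: logits. Default synthetic value 0.8.
* $\pi$ — a single structural-zero probability shared across cells
  (intercept-only zero-inflation): some replicates fail entirely for
  reasons unrelated to the binomial hatch process.

The integral is evaluated by Gauss–Hermite quadrature. The default order
is 40: we measured plain (non-adaptive) quadrature error against
adaptive numerical integration and found order 25 leaves log-likelihood
errors of a few times $10^{-6}$ at $\sigma \approx 0.8$, while order 40
is below $10^{-7}$ across the parameter ranges the optimizer visits;
order 40 keeps the likelihood within the $10^{-6}$ bound our acceptance
tests demand at a 1.6× cost. Adaptive (mode-centred) quadrature was
deliberately not used: the saturated cell means keep the integrand
well-centred, and a fixed rule keeps the likelihood a smooth, exactly
reproducible function of the parameters.

Optimization is L-BFGS-B over $(\eta_1,\dots,\eta_C, \log\sigma,
\mathrm{logit}\,\pi)$ with three starts (the best log-likelihood wins).
Degenerate cells — all eggs hatched, or none — have no finite logit
optimum, so cell logits are box-constrained to $\pm 8$ (odds of about
3000:1) and cells ending on the boundary are flagged. The covariance of
the estimates is the inverse of the numerically differentiated observed
information; if that matrix is singular a pseudo-inverse is used and the
fit is flagged.

**Zero-inflation fallback.** When the data contain no zero-hatch
replicate, $\pi$ is unidentifiable (the likelihood is monotone in $\pi$),
so the zero-inflated fit cannot converge meaningfully; the package then
fits the plain overdispersed-binomial model and records
`zero_inflated = FALSE`. The same fallback triggers on optimizer failure
or singular information.

**Inference.** Contrasts are Wald on the link scale with back-transformed
endpoints, matching standard estimated-marginal-means practice: CI
strength $OR_{CI}$ (CI vs compatible), rescue $OR_R$ (rescue vs
compatible), and the temperature contrast
$OR_{CI,T} = OR_{CI,\mathrm{cool}} / OR_{CI,\mathrm{warm}}$, a
double-difference of four cell logits. Reported $\chi^2$ statistics are
Wald (the likelihood-ratio alternative is not implemented); effect sizes
use $\eta^2_p = \chi^2 / (\chi^2 + n)$ with $n$ passed explicitly, since
per-subset observation counts are not recoverable from a fit alone.

**Type-II tests on an incomplete factorial.** Some strain × temperature
cells are never reared (two of the host species cannot complete
development at the coolest temperatures), so the factorial is incomplete.
Each term's hypothesis space is built at the cell level: the term's
design columns (row-wise products of sum-to-zero codings) are
residualized against the span of every term that does not contain it, and
the Wald statistic is formed on an orthonormal basis of the remainder,
with degrees of freedom equal to its rank. On complete balanced designs
this reproduces sequential (type-I) statistics exactly — a property the
test suite asserts against an independent construction — and on
incomplete designs it reduces the df of the affected terms with a
warning rather than silently inflating them.

**FDR families.** The paper-style analysis corrects contrasts within an
analysis question, so the pipeline declares one family per question (all
CI-vs-compatible contrasts; all rescue contrasts; all within-strain
temperature contrasts) and applies Benjamini–Hochberg within each.

# Development time by permutation

Several strain–temperature–cytotype cells have zero within-group
variance (every vial emerged at the same monitoring check), which rules
out Gaussian ANOVA. Two permutation tools are used instead:

* `permutation_diff_test()` — mean difference with p-value equal to the
  proportion of permuted $|\Delta|$ at least the observed one, and the
  exact floor $1/(n_{\mathrm{perm}}+1)$ when no permutation reaches it.
  The floor convention is the pure proportion (observed statistic not
  added to the numerator), which is the stated convention of the
  analysis this package implements, even though the add-one convention
  is more common. Note the floor binds only when groups are large enough
  that random reshuffles essentially never regenerate the observed
  labelling (for small groups the observed split recurs by chance and
  counts as an exceedance).
* `permanova_seq()` — Euclidean-distance PERMANOVA with sequential
  (type-I) sums of squares from Gower-centred inner products, free
  permutation of observations, and $p = (\#\{F^* \ge F\} + 1) /
  (n_{\mathrm{perm}} + 1)$. For a univariate response the pseudo-F equals
  the classical ANOVA F algebraically; the tests assert this identity and
  agreement with an independent implementation. Restricted permutation
  schemes are out of scope.

Development-time uncertainty is summarized by bootstrap percentile
intervals of the mean (10,000 resamples); groups with zero variance get
a flagged degenerate interval. BCa intervals were not used — the
resample count is specified by the procedure we mirror, the interval
type is not, and percentile is the simplest defensible default.

# Relative quantification

$\Delta C_q$ arithmetic is deterministic: triplicates are aggregated by
arithmetic mean (the aggregation rule is not specified by the source
procedure; an optional max-spread outlier rule — drop the farthest well
when the spread exceeds one cycle — is available but off by default),
fold-change is $2^{-\Delta C_q}$, and multi-variant Wovirus densities are
summed on the fold scale *before* any log transform, so the total is at
least the largest variant. Zero ddPCR target concentrations cannot be
log-transformed and are treated as missing for log-scale models rather
than imputed. No amplification-efficiency correction or plate
normalization is applied.

Log2 densities and transcript abundances are fitted by factorial OLS
with saturated cell means (computed in closed form), type-II F tests via
nested least-squares comparisons with the error mean square from the
full model, partial $\omega^2$ effect sizes
($(ss - df\,ms_e)/(ss + (n - df)\,ms_e)$, floored at zero for reporting
with the raw value retained), and pairwise $RR = 2^{\Delta}$ contrasts
with $t$-based intervals on the residual df.

# Concordance

Within-strain concordance between temperature-induced changes in two
quantities propagates EMM uncertainty by Monte Carlo: each iteration
draws every condition value independently from
$\mathrm{Normal}(\widehat{\mathrm{EMM}}, SE^2)$, computes tie-corrected
Kendall $\tau_b$, pools iterations on the Fisher-z scale (clipping
$|\tau|$ at $1 - 10^{-6}$, since $|\tau| = 1$ occurs with positive
probability at two conditions and $\mathrm{atanh}$ would diverge), and
back-transforms. The probability of direction is the fraction of
iterations agreeing in sign with the point estimate; exact-zero $\tau$
iterations count toward neither sign, and a point estimate of exactly
zero reports $p_d = 0.5$. Draws are independent across conditions and
across the two variables; the correlation the EMMs inherit from a shared
model fit is deliberately ignored, mirroring the procedure this package
implements. When every SE is zero the sampler is skipped and the exact
$\tau_b$ of the means is returned.

# Phylogenetic regression

Cross-strain regressions must respect shared ancestry: two closely
related strains are not independent observations. The model is

$$
y_i = \alpha + \beta x_i + b_{s(i)} + \varepsilon_i,\qquad
b \sim \mathrm{N}(0, \sigma^2_{\mathrm{phylo}} A),\qquad
\varepsilon_i \sim \mathrm{N}(0, \sigma^2_{\mathrm{resid}}),
$$

with $A$ the Brownian-motion covariance read off an ultrametric
chronogram: $A_{jk}$ is the shared root-to-MRCA branch length. $A$ is
normalized to unit diagonal (correlation form) before fitting so that
$\sigma^2_{\mathrm{phylo}}$ carries the scale and results do not depend
on the chronogram's arbitrary relative age.

Priors are weakly informative defaults — improper flat on $\alpha$ and
$\beta$, half-Student-t(3, 0, 2.5·sd(y)) on both SDs — and are
config-exposed, since the procedure we mirror does not state its priors.
The sampler is Gibbs for the joint location block $(\alpha, \beta, b)$
(its full conditional is multivariate normal) with stepping-out slice
updates on $\log\sigma_{\mathrm{phylo}}$ and
$\log\sigma_{\mathrm{resid}}$; no Hamiltonian dynamics is involved, so
there is no analogue of an acceptance-divergence tuning parameter. Four
chains of 8,000 iterations (2,000 warmup) give 24,000 kept draws by
default. Summaries are the posterior mean slope, equal-tailed 95%
credible interval (an HPD interval was not chosen because the procedure
names only a "95% credible interval"), Bayesian $R^2$ (per-draw
$\mathrm{Var}(\mathrm{fitted})/(\mathrm{Var}(\mathrm{fitted}) +
\sigma^2_{\mathrm{resid}})$ with fitted values including the strain
intercepts), probability of direction relative to the posterior mean's
sign, and max split R-hat over all parameters with a warning at 1.01.
One seed per chain is derived from the master seed.

# The synthetic-data generators

The generators produce data *from the models the analyses assume*, which
makes them the right instrument for calibration tests and the wrong one
for claiming robustness: passing tests show the estimators are correct
and calibrated under the assumed data-generating process, not that the
models are adequate for any particular real dataset (no plate effects,
no amplification-efficiency drift, no non-Gaussian OLRE, no model
misspecification).

Default conditions mirror the study design being emulated: 8 strains ×
up to 4 temperatures (18–26 °C; one strain missing the coolest
temperature, one reared at only two) × 3 cross types, 15 replicates per
cell (about 1,300 crosses); per-replicate egg totals are negative
binomial truncated at one egg with mean 24 — matching the printed totals
of roughly 33,000 embryos over 1,339 crosses — and dispersion 5, a
stand-in since per-replicate egg-count distributions are not published.
The minimum-10-embryo filter is applied downstream by
`filter_min_eggs()`, not in the generator. Default CI odds ratios per
strain–temperature cell follow the published magnitudes for the
temperature-sensitive strains and plausible strong-CI values elsewhere;
$\sigma = 0.8$ and $\pi = 0.05$ are bench-plausible choices made once.
Development times are linear in temperature (−1.1 days/°C around a
13-day baseline at 23 °C) with a small symbiont acceleration, snapped
*up* to an every-other-day monitoring grid (configurable phase); Cq
triplicates add Normal noise (SD 0.3 cycles) at both the sample and well
level; ddPCR spike-ins are lognormal. A single master seed expands into
per-generator child streams (`child_seed()`), so adding a generator
never perturbs another's output. Undetermined Cq wells are not simulated
by default.

# Numerical choices and degenerate inputs

* Likelihood values are floored at $10^{-300}$ before logging; a
  non-finite record raises an error naming its index.
* Variance parameters are optimized as $\log\sigma$ (bounded away from
  zero at $10^{-3}$) and $\mathrm{logit}\,\pi$.
* PERMANOVA on a constant response short-circuits to zero $R^2$ for all
  terms, $p = 1$.
* RR contrasts on an exact-fit model (zero residual variance) report
  $p = 1$ for zero differences instead of 0/0.
* Permutation tests on groups with no variation return $p = 1$.
* All-tied vectors make Kendall $\tau$ undefined; the package returns
  `NA` with a warning rather than a value.

# Problem sizes in the test suite

The suite favours fixed-seed, reduced-scale studies chosen for stable
Monte-Carlo error: 200 simulated experiments (8 cells × 30 replicates)
for Wald-coverage of the hatch model; 2,000 null replicates for
permutation and Pearson type-I error; 100 repeats each for the PERMANOVA
variance-share and phylogenetic-regression coverage studies (n = 29
observations over 8 strains, 2 chains × 1,200 iterations per fit, since
interval coverage needs far fewer draws than a production fit); pipeline
determinism is asserted on a 2-strain × 2-temperature design. The full
default-scale pipeline (all 8 strains, 9,999 PERMANOVA permutations,
4 × 8,000 MCMC iterations) completes in a few minutes on one CPU via
`run_pipeline(pipeline_config(out_dir, seed))`.

# Known limitations

* No random-slope or nested random-effect structures in the hatch model;
  no simulation-based residual diagnostics.
* PERMANOVA implements Euclidean distance and free permutation only.
* The concordance procedure ignores cross-condition covariance of EMMs.
* The phylogenetic model is single-predictor Gaussian; Pagel's λ is not
  estimated, and the optional second (temperature) random intercept is
  not implemented.
* qPCR efficiencies are assumed equal to 2 (the $2^{-\Delta C_q}$
  method); no standard curves, no between-plate normalization.
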