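---
title: "Methods: diagonal reference models for DNAm age acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagonal reference models for DNAm age acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmage)
```

# The scientific question

Socio-economic position (SEP) in childhood and adulthood are both
associated with DNA-methylation measures of biological aging. Because
social mobility is a deterministic function of origin and destination
class, an ordinary regression with all three is unidentified; the diagonal
reference model (DRM) resolves this by treating the *immobile* (diagonal)
groups as the benchmark and modelling the mobile groups as a mixture of
their origin and destination benchmarks. `drmage` implements that model
together with everything needed to take it from a raw beta-value matrix to
fitted mobility models: clock evaluation, cell-composition adjustment,
residual age acceleration, class and mobility coding, descriptive
surfaces, and a synthetic-cohort generator for validation.

# The model

For a person with origin class $i$ and destination class $j$,

$$\mathrm{E}(Y_{ij}) = \beta_0 + p\,\mu_{ii} + (1-p)\,\mu_{jj} + X_{ij}\beta,$$

where $Y$ is residual age acceleration, $\mu_{kk}$ are the diagonal
(immobile) class means, $X$ holds covariates and optional mobility
dummies, and $p \in [0,1]$ is the **origin weight**: $p = 1$ means the
outcome depends only on childhood class, $p = 0$ only on adult class.

**Identification.** As written, $\beta_0$ plus three free diagonal means
is over-parameterized (adding a constant to all $\mu_{kk}$ and subtracting
it from $\beta_0$ changes nothing). We use sum-to-zero class effects:
$\mu_{kk} = \beta_0 + \delta_k$ with $\sum_k \delta_k = 0$. This matches
the convention of published DRM tables, in which the three printed class
estimates sum to approximately zero, and makes the constant interpretable
as the covariate-adjusted grand diagonal mean.

**Estimation.** At fixed $p$ the model is linear: each person's class-
effect design row is $p$ times the sum-to-zero coding of the origin class
plus $(1-p)$ times that of the destination class (immobile persons get
their class coding with total weight one). `fit_drm` therefore profiles
the Gaussian log-likelihood over $p$: closed-form least squares on the
grid $p = 0, 0.01, \dots, 1$, followed by Brent refinement of the best
grid point to a tolerance of $10^{-6}$. The profile is one-dimensional
and each inner fit is a small OLS, so this is cheap and — unlike joint
nonlinear optimization — global in $p$ by construction. With
$\hat\sigma^2 = \mathrm{RSS}/n$ (the ML variant), the maximized
log-likelihood is $-\tfrac n2(\log(2\pi\hat\sigma^2) + 1)$.

**Inference.** Standard errors come from the inverse numerical Hessian of
the full log-likelihood in $(p, \delta_1, \delta_2, \beta_0, \beta,
\sigma^2)$ at the optimum, so the reported uncertainty in $\delta$ and
$\beta$ reflects the estimation of $p$ (and vice versa). Confidence
intervals are Wald at 95%. When $\hat p$ lies within 0.005 of a boundary
the Wald interval for $p$ is reported as `NA` rather than truncated,
because Wald theory fails on the boundary. AIC $= -2\ell + 2k$ and
BIC $= -2\ell + k\log n$ count $k$ as $p$, two free class effects, the
constant, the covariate coefficients, and $\sigma^2$; this convention is
applied identically across the four mobility specifications, so
comparisons are internally consistent.

**Mobility specifications.** Four nested specifications mirror standard
practice: (1) no mobility term; (2) a single any-mobility indicator;
(3) upward and downward indicators; (4) one-step and two-step indicators
by direction. The dummies are deterministic functions of origin and
destination rank and are generated internally (`encode_mobility`);
identities such as `upward + downward = mobile` and
`up1 + up2 = upward` hold by construction and are enforced by tests.

**Degenerate inputs.** A sample with no mobile person leaves $p$
multiplying nothing identifiable; `fit_drm` raises an identifiability
error rather than returning an arbitrary weight. Rank-deficient designs
(e.g. a covariate collinear with a mobility dummy) are an error naming
the aliased columns. A numerically flat profile (all grid log-likelihoods
within $10^{-9}$) deterministically returns the smallest tied $p$, with a
warning. Fits whose Hessian cannot be inverted are flagged
`converged = FALSE`, never returned silently.

# Upstream stages

**Clocks.** A clock is a fixed linear predictor
$\mathrm{intercept} + \sum_i \beta_{ij}\,\mathrm{coef}_i$ over a CpG set.
Probes absent from the supplied matrix are dropped from the sum *without
rescaling* — the convention used when clocks trained on older arrays are
applied to EPIC data — and the dropped count is reported per clock, so a
handful of missing training probes is visible rather than silent. An `NA`
beta for a present probe drops that term for that sample only, mirroring
the probe-level policy at sample granularity. Published coefficient sets
are user-supplied files (two columns, probe and coefficient, one
`(Intercept)` row); small all-positive toy clocks are generated in code
for tests.

**Cell composition.** Reference-based deconvolution solves, per sample,
$\min_w \lVert b - Rw \rVert^2$ subject to $w \ge 0$ and $\sum w \le 1$
(inequality, not equality, following the standard quadratic-programming
formulation). Because the number of cell types $K$ is small, the convex
QP is solved *exactly* by enumerating candidate active sets: for every
subset of zeroed fractions, with the sum constraint slack or tight, the
equality-constrained stationary point is closed-form; the feasible
candidate with the least objective is the global optimum. The solve
operators depend only on the reference, so they are factored once and
applied to all samples at once. Reference construction (probe selection
from sorted-cell data) is out of scope; the reference is taken as given,
making the module reference-agnostic.

**Age acceleration.** OLS residuals of DNAm age on chronological age,
plate dummies (first level reference) and cell fractions. Residuals have
mean zero and are orthogonal to every regressor by construction; both are
asserted in tests at $10^{-6}$. Residualization is redone after any
sample exclusion so the analytic-sample mean re-zeroes, and pace-type
predictors (values near 1.0/year) are residualized identically to
age-scale clocks — units are then "pace units", not years. Whether the
two profiling batches should be residualized jointly or separately is not
determinable from the published description; plate dummies are assumed to
absorb dataset-of-origin, which joint residualization with plate effects
achieves.

**Class and covariates.** Classes are the three collapsed NS-SEC
categories, ordered disadvantaged < intermediate < advantaged. Household
class uses the dominance rule (most advantaged available member; a single
available member stands alone). The analytic filter keeps age ≥ 25 (the
boundary is inclusive: "below 25" is excluded) with complete origin,
destination, sex and age, logging counts per reason. `z_age` standardizes
age over the analytic sample with the $n-1$ SD — the published tables are
silent on the denominator; the sample SD is the conventional choice — and
the squared term is the square of the standardized age (squaring after
standardizing, per the covariate definition). Birth-cohort stratification
splits at 1956 with persons born exactly in 1956 assigned young by
default (the published text and table disagree on this boundary; the
choice is exposed as an argument), re-standardizing within stratum.

# The synthetic generator

`generate_cohort` emulates the study conditions: the published
origin × destination cell counts (432, 234, 302 / 467, 466, 903 / 42, 76,
218; n = 3140) assigned *exactly* rather than by multinomial draws (so
marginal checks are exact and fixtures reproducible), age from
N(54.5, 14²) truncated at 25 years, 55.8% female, uniformly assigned
plates (default 8; plate count is not reported and only needs to exercise
the batch adjustment), and outcomes drawn from the DRM equation with
chosen truth. The default truth — $p^* = 0.5$, $\delta^* = (1, 0, -1)$,
$\beta_0^* = 0$, female effect $-1$, $\sigma = 1$ — is an arbitrary but
field-plausible choice near the magnitudes seen in published DRM tables
for second-generation clocks; it is fixed once and documented here.

`generate_betas` inverts the clock equation: all clock probes get the
base level $(target - I)/S$ ($S$ the coefficient sum), plus a per-sample
perturbation lying in the orthogonal complement of the coefficient vector
and the ones vector — so betas vary probe-to-probe and sum to the same
weighted total, and the clock recovers every target to $10^{-10}$.
Perturbations are shrunk per sample where needed to keep betas inside
$[0,1]$, which preserves orthogonality exactly. `simulate_study` composes
cohort, clock, clock-probe betas (targets = age + plate effect +
outcome), reference-mixture probes with known cell fractions, and filler
probes into one self-consistent dataset.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genome-scale beta distributions and probe-level
biology, non-Gaussian outcome tails, informative missingness,
confounding between class and age or plate, and measurement error in
class reporting. Tests against the generator validate the *estimators*
(recovery of known truth under the model's own assumptions), not the
substantive findings.

# Descriptives

Cross-tabs report per-cell arithmetic means and counts with
cell-n-weighted marginals; `marginal_from_cells` recomputes marginals
from any cells-and-counts pair, which makes published tables' internal
arithmetic checkable. Display rounding is half-away-from-zero to 2
decimals (matching printed tables); full precision is kept internally.
Note that a marginal recomputed from cells *already rounded* to 2 dp
carries propagated rounding error of up to half a printed unit, so a
printed total can legitimately differ from the cell-derived total by one
unit in the last digit. Group comparisons use the classical
pooled-variance t-test (the published methods say only "two sample
t-test"; the classical form is chosen and documented — only descriptive
p-values depend on it) and one-way ANOVA. The restricted comparisons
(downward vs stable-advantaged; upward vs stable-disadvantaged) are OLS
on the group indicator plus sex, `z_age`, `z_age2`.

# Problem sizes and reproducibility

Simulation-based checks use the full published cell structure
(n = 3140) for single-fit recovery, 100 replicates for the BIC
model-selection study, and 200 probes / 3 cell types for deconvolution
recovery — sizes at which the profile estimator's sampling SD for $p$ is
about 0.02–0.04 (depending on the class-effect spread), small enough to
make recovery informative while keeping the full suite fast. Every
generator is a pure function of its arguments including the seed;
`run_pipeline` is byte-deterministic for fixed inputs.

# Known limitations

* Gaussian ML only: no multinomial/ordinal outcomes, random effects,
  survey weights, or bootstrap inference (Wald only).
* The DRM may understate mobility effects by construction, since the
  mobility dummies compete with the class mixture for the same variation.
* Boundary inference on $p$ is not available (flagged, not approximated).
* Raw-array QC/normalization, IDAT parsing and clock training are out of
  scope; inputs are assumed normalized beta values.
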