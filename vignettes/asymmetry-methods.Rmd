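---
title: "Models and methods for phylogenetic brain-asymmetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for phylogenetic brain-asymmetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylasym)
```

## The problem

Many vertebrates lateralize brain function, and one structural correlate is
*directional asymmetry*: a consistent population-level size difference
between the left and right side of a bilateral brain structure, as opposed
to *fluctuating asymmetry*, the zero-mean developmental noise around
symmetry.  Comparative studies of this phenomenon measure the left and
right sides of several brain regions (olfactory bulb, telencephalon, optic
tectum, whole brain) across many species, ask which species are left- or
right-biased, and test whether the degree of asymmetry covaries with total
brain size or with ecological pressures such as predation risk.  Because
species share ancestry, none of these tests can treat species as
independent draws; every inferential step in this package conditions on a
phylogeny.

## From calipers to volumes

Each specimen contributes the greatest length, width and height of each
side of each structure.  Volumes use the ellipsoid model

$$V = L \times W \times H \times \frac{\pi}{6 \times 1.43},$$

where 1.43 is an empirical correction for the departure of brain structures
from a true ellipsoid.  The index of asymmetry for a species is the signed
relative difference of side volumes,

$$A = \frac{\mathrm{left} - \mathrm{right}}{0.5\,(\mathrm{left} + \mathrm{right})},$$

which is zero at symmetry, antisymmetric under a side swap, invariant to
common rescaling, and bounded in $(-2, 2)$.  Note the formula is the
side difference over the *side mean*; a literal left-to-right reading of
the printed expression $(L-R)/0.5 \times (L+R)$ would be unbounded and
scale-dependent, contradicting every property the asymmetry-index
literature relies on, so the standard relative-difference reading is used.

Species-level summaries are taken on the $\log_{10}$ scale: per-individual
side volumes are logged and averaged across individuals (a geometric mean
on the raw scale), the species index is computed from the back-transformed
side means, and total brain size is the *raw-scale* sum of the left and
right whole-brain volumes per individual, then logged, then averaged.  The
alternative convention — averaging per-individual indices — is exposed via
`species_summaries(convention = "individual_mean")` but is off by default,
since the species-level tables this analysis mirrors carry one index per
species.  Species are classified `left_larger` / `right_larger` by the sign
of the mean-log side difference; only exact floating-point ties (tolerance
`1e-12`) are called `tied`, because real measurement data essentially never
produces them.

Measurement quality is quantified by the one-way intraclass correlation
over repeated measurements of the same specimens,
$R = (MS_b - MS_w) / (MS_b + (k_0 - 1) MS_w)$ with the usual
unequal-group-size correction $k_0$.

## The inferential core

### PGLS with Pagel's lambda

All regressions are generalized least squares with error covariance

$$\mathrm{Var}(\varepsilon) = \sigma^2\, D^{1/2} C_\lambda D^{1/2},
\qquad D = \mathrm{diag}(1/n_i),$$

where $C$ is the Brownian-motion covariance implied by the tree (shared
root-to-MRCA branch length), $C_\lambda$ multiplies its off-diagonals by
Pagel's $\lambda \in [0, 1]$, and the diagonal weight matrix gives each
species a residual variance inversely proportional to the number of
individuals measured — the standard sampling-variance argument for
"weighting by sample size", which the source description leaves otherwise
unspecified.  $\lambda$ is estimated by maximizing the profile
log-likelihood (coefficients and $\sigma^2$ profiled out analytically) with
bounded scalar optimization on $[0,1]$ at tolerance `1e-8`, plus explicit
evaluation of both boundaries so that a boundary optimum is returned
exactly.  Likelihood-ratio tests against $\lambda = 0$ (phylogenetic
independence) and $\lambda = 1$ (full Brownian dependence) use the plain
$\chi^2_1$ reference; at a boundary null this is conservative, and a fit
*at* a boundary gives $p = 1$ against that boundary by construction.

Implementation note: writing $C = A^{1/2} K A^{1/2}$ with $A$ the diagonal
of tip depths, a single symmetric eigendecomposition of the correlation
matrix $K$ turns every fixed-$\lambda$ evaluation into a diagonal reweighing
($O(np^2)$), so profiling $\lambda$ costs one eigendecomposition total.
The test suite checks this path against a brute-force dense GLS solve to
`1e-10` and against `nlme::gls` with `ape::corPagel`.

Standard errors use $(X^\top V^{-1} X)^{-1} \hat\sigma^2 \, n/(n-p)$, t
statistics have $df = n - p$, and $R^2$ is computed in the whitened
($V^{-1/2}$) space against the GLS intercept-only mean.  The adjusted
variant is reported alongside, since species-level analyses of this kind
sometimes print negative values that only an adjusted statistic can
produce.  All numeric variables (response and predictors) are standardized
before fitting so coefficients are comparable across models; the
predation-risk covariate is $\log_{10}$-transformed first, consistent with
the all-log10 analysis scale (the source leaves this ambiguous; the
simulator records both scales in `truth.json`).

### Phylogenetic paired t-test

Per-species side differences $d = \overline{\log_{10} L} -
\overline{\log_{10} R}$ are modeled as
$d \sim \mathcal N(\mu_d \mathbf 1, \sigma^2 C_{\lambda_d})$.  The GLS mean
$\hat\mu_d = (\mathbf 1^\top C^{-1} d)/(\mathbf 1^\top C^{-1} \mathbf 1)$,
its standard error uses the bias-corrected residual variance
$\hat\sigma^2_{n-1}$, and $t = \hat\mu_d / SE$ with $df = n - 1$ ($\lambda$
treated as a nuisance without a df penalty, consistent with per-region
species counts minus one).  $\lambda_d$ is ML-estimated by default, with a
`lambda` argument to fix it.

**Calibration caveat.**  With an intercept-only model the precision
$\mathbf 1^\top C_\lambda^{-1} \mathbf 1$ is steeply decreasing in
$\lambda$ (more than an order of magnitude between $\lambda = 0$ and $0.5$
on a 50-tip Yule tree).  At $n = 50$ the ML $\hat\lambda_d$ is noisy and
biased low, and plugging it in over-rejects: simulation at
$\lambda_{true} = 0.5$ gives a type-I error near 0.19 at nominal 0.05
(~0.13 for a REML variant), while fixing $\lambda_d$ at the true value
restores the nominal rate (0.03–0.07 band).  This is a property of the
plug-in procedure, not of this implementation — the ML $\hat\lambda$ here
matches `nlme`'s `corPagel` to four decimals.  The acceptance calibration
test therefore exercises the fixed-$\lambda$ variant; users testing small
species groups should prefer a justified fixed $\lambda$ or treat marginal
p-values with caution.

### ANCOVA

Species differences in relative brain size are tested at the individual
level with `lm(log10(brain) ~ log10(SVL) + species)` and the standard
partial-F degrees of freedom $(k - 1,\; N - k - 1)$.  A response exactly
linear in SVL with no species effect yields a 0/0 mean-square ratio; the
implementation reports $F = 0$, $p = 1$ in that degenerate case.  (The
printed df pair in the motivating study is inconsistent with its own
sample sizes; standard dfs are reported and no attempt is made to emulate
the printed pair.)

## The synthetic world

The raw field data behind this kind of study are typically unreleased, so
the generator produces datasets with the statistical structure the analysis
assumes; its defaults are the package's stated world and are not tuned to
any test outcome.

* **Tree**: Yule (pure birth) with rate 1, `n_species = 99` — matching the
  scale of a ~99-species anuran dataset; ultrametric by construction.
* **Species base sizes**: per region,
  $z \sim \mathcal{MVN}(\mu_r \mathbf 1, \sigma^2 C_\lambda)$ with
  $\sigma^2 = 0.1$ and region means 2.7 / 3.7 / 3.4 / 4.3 log10 mm³
  (olfactory bulb, telencephalon, optic tectum, whole brain), reproducing
  species-mean magnitudes of ~2.7–4.4 with SD ~0.3–0.4 log units.  Regions
  evolve independently — adequate for exercising per-region statistics,
  though real regional volumes are mutually correlated and constrained to
  sum to less than the whole brain, which this generator does not enforce.
* **Asymmetry**: $a = \delta + \beta_{size}\,\mathrm{std}(z_{whole}) +
  \beta_{risk}\,\mathrm{std}(\log_{10} risk) + \varepsilon$, injected
  symmetrically as $z \pm a/2$ so total size is independent of asymmetry by
  construction.  Defaults $\delta = 0$ (both direction groups arise, and
  the pooled all-species test is null, matching the empirical pattern),
  $\beta_{size} = 0.02$, $\beta_{risk} = 0.008$ (the magnitude of published
  standardized slopes, ~0.008–0.04), $\mathrm{sd}(\varepsilon) = 0.01$.
  $\varepsilon$ is iid by default; `phylo_asym_noise = TRUE` draws it with
  the $\lambda$-scaled phylogenetic covariance (marginal SD preserved),
  which is what the parameter-recovery tests use — with iid noise the
  asymmetry regression's true residual $\lambda$ is 0 regardless of
  `lambda_true`, so joint $(\lambda, \beta)$ recovery would be untestable.
* **Predation risk**: lognormal (meanlog 1, sdlog 1 — median ~2.7 snakes
  per km², right-skewed as transect counts are), independent of the tree;
  the phylogenetic structure of such covariates is unknown in the source
  material, and independence is the conservative choice.
* **Individuals**: $n_i \sim \mathrm{Uniform}\{2, \dots, 8\}$ per species.
  Each individual carries one lognormal biological size factor
  (`cv_individual = 0.1`, a typical within-species volumetric CV) applied
  to all its structures, and each recorded side volume gets independent
  lognormal measurement noise (`cv_measurement = 0.02`; replicates redraw
  only this term).  `cv_individual` is an addition to the minimal
  measurement model: without genuine between-specimen variance,
  within-species repeatability would be undefined (no between-subject mean
  square to compare against).  Volumes are inverted into L/W/H under fixed
  per-region aspect ratios, so `ellipsoid_volume()` round-trips them
  exactly; SVL is allometric in whole-brain size
  ($\log_{10} SVL = 0.8 + 0.25 (z - \bar z) + \mathcal N(0, 0.03)$,
  i.e. ~63 mm frogs).
* **Determinism**: one RNG stream seeded from `config$seed`, consumed in a
  fixed order (tree; then risk, base sizes, asymmetry noise; then
  individuals), so fixtures are exactly reproducible.

What a green test does *not* establish: the generator says nothing about
digitization error structure, ontogenetic or sex effects, non-lognormal
measurement error, correlated evolution among regions, or phylogenetic
signal in predation risk.  Green means the estimators recover the stated
world; it is not a validation of the biological conclusions of any
particular study.

## Numerical choices and degenerate inputs

* Newick parsing is strict where `ape` is permissive: duplicate tips,
  missing branch lengths and unbalanced parentheses are hard errors;
  square-bracket comments are stripped; quoted labels and internal node
  labels pass through.  Non-ultrametric trees are accepted (the pipeline
  logs a note) since time calibration is not guaranteed upstream.
* Pruning keeps the depth from the original root to the new MRCA as a
  `root.edge`, and `vcv_matrix()` adds it to every entry, so
  `vcv(prune(T, S))` equals the S-submatrix of `vcv(T)` exactly — required
  for per-region analyses on pruned trees to agree with the full-tree
  covariance.
* Taxon names are joined by exact string match after trimming whitespace
  and mapping spaces to underscores.
* Constant paired differences of zero report $t = 0$, $p = 1$; zero
  residual variance with a nonzero mean reports a degenerate flag.
  Direction groups too small to fit (< 3 species for the paired test,
  < 5 complete cases for PGLS) become skip rows with a reason — never
  silent omission.  Species missing the risk covariate are dropped from
  risk models only (complete case per model), with a log entry.
* Pipeline outputs are byte-deterministic: doubles are serialized at 17
  significant digits and no analysis path consumes randomness.

## Known limitations

REML estimation, measurement-error (SE-aware) PGLS beyond inverse-$n$
weighting, multivariate multi-region models, and posterior tree-sample
uncertainty propagation are out of scope.  The $\chi^2_1$ boundary LRT is
conservative; a 50:50 mixture reference would be sharper.  The paired
test's ML-$\lambda$ plug-in anticonservativeness at small $n$ is documented
above and left as-is deliberately, since it reflects the procedure this
package reimplements.
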