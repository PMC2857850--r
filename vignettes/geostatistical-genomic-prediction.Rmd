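---
title: "Genomic prediction with ridge regression and geostatistical kernels"
author: "gskernel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with ridge regression and geostatistical kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-wide selection (GS) predicts breeding values from a genome-spanning
marker panel by estimating the effects of all chromosomal segments
simultaneously, instead of testing markers one at a time.  `gskernel`
implements one family of GS methods that can live entirely inside standard
mixed-model machinery: ridge regression (RR) and its geostatistical
extensions, in which the genetic correlation between two individuals is a
decreasing function of the *distance* between their marker genotypes, exactly
as spatial correlation decays with distance in geostatistics.

The package targets two-generation cross designs: a handful of fathers mated
to a set of mothers, a large offspring population genotyped at biallelic
markers, a phenotyped subset with a few repeated measurements along a growth
curve, and the task of predicting the unphenotyped offspring's breeding
values at a time beyond the last measurement.

## Stage 1: growth-curve extrapolation

Each phenotyped individual $i$ has observations $y_{it}$ at a handful of
times.  `growth_extrapolate()` fits, separately per individual, the
three-parameter logistic mean

$$E(y_{it}) = \frac{\alpha_i}{1 + \beta_i e^{-\gamma_i t}},$$

by nonlinear least squares ($\alpha$ = asymptote, $\beta$ = shape, $\gamma$ =
rate; this parameterization leaves exactly 2 error degrees of freedom per
5-point series).  The residual variance is then pooled across individuals,
$\hat\sigma^2 = \sum_i \mathrm{RSS}_i / \sum_i \mathrm{df}_i$ (with five
times this is $\mathrm{RSS}/2n$), and every curve is extrapolated to the
target time with a delta-method standard error
$\mathrm{se}^2 = \hat\sigma^2 \, \nabla^\top (J^\top J)^{-1} \nabla$, where
$J$ is the Jacobian at the least-squares optimum and $\nabla$ the gradient of
the mean curve at the target time.  Fixing the residual variance at the
pooled estimate does not move the least-squares optimum — it only rescales
the parameter covariance — so the "second pass" is a covariance computation,
and the package asserts this invariance in its tests.  The squared standard
errors travel downstream as *known within-individual error variances*.

Numerical choices: starting values are derived deterministically from each
series (asymptote from the maximum, rate from the observed rise, shape from
the first observation) with a fixed fallback grid of rates, so the stage is
seedless and reproducible; the Levenberg–Marquardt algorithm handles
zero-residual (noise-free) series; a singular $J^\top J$ flags the individual
with infinite prediction variance and it is excluded downstream with a
warning; constant series return a flagged boundary fit.

## Stage 2: the kernel mixed model

For the stage-1 predictions $y_i$ of the $n$ phenotyped individuals,

$$y_i = \mu + g_i + v_i + e_i,$$

where $g$ is the marker-explained genetic effect with
$\mathrm{var}(\mathbf g) = \sigma^2_g \, \Gamma$, $v$ an independent polygenic
effect, and $e$ the residual.  Markers are coded $z_{ik} \in \{-1, 0, 1\}$
(homozygote / heterozygote / other homozygote) in a matrix $Z$, and

* **ridge regression**: $\Gamma = ZZ^\top$ — the BLUP of $g$ equals
  $Z\hat u$ with $\hat u = (Z^\top Z + \lambda^2 I)^{-1} Z^\top (y - \hat\mu)$
  and penalty $\lambda^2 = \sigma^2_e / \sigma^2_g$;
* **geostatistical kernels**: $\Gamma_{ii'} = f(d_{ii'})$ with
  $d_{ii'} = \lVert \mathbf z_i - \mathbf z_{i'} \rVert$ and $f$ one of

  | name | $f(d)$ |
  |---|---|
  | linear | $(1-\theta d)\,\mathbb 1(\theta d \le 1)$ |
  | quadratic | $(1-\theta d^2)\,\mathbb 1(\theta d^2 \le 1)$ |
  | power | $\theta^d,\ \theta\in(0,1)$ |
  | exponential | $e^{-d/\theta}$ |
  | gaussian | $e^{-d^2/\theta^2}$ |
  | spherical | $(1 - 1.5\,d/\theta + 0.5\,(d/\theta)^3)\,\mathbb 1(d \le \theta)$ |

  (the standard spatial structures of mixed-model software);
* **independent**: $\Gamma$ omitted.

Two residual conventions are supported.  In **pooled** mode (default) the
residual error and the polygenic effect are not separately identifiable —
both contribute an iid term — so a single free variance absorbs them and is
reported as the residual variance $\sigma^2_e$.  In **fixed** mode the
stage-1 squared standard errors enter as a *known* heterogeneous diagonal
$\mathrm{diag}(\mathrm{se}^2_i)$ and the free iid variance is the genuinely
polygenic $\sigma^2_v$.  This identifiability constraint is why a pooled RR
fit counts $q = 2$ free covariance parameters (not 3): fitting
$\sigma^2_v I + \sigma^2_e I$ jointly would leave the optimizer on a flat
ridge.

An optional pedigree switches on the extended covariance
$\Omega = \sigma^2_f V_f + \sigma^2_m V_m + \sigma^2_c V_c$, where
$V_f[i,i'] = 1$ iff $i$ and $i'$ share the father (likewise mother and
cross = father-by-mother pair), diagonal 1.  This is identical to grouped
random effects via 0/1 incidence matrices, a fact the tests exploit as an
independent oracle.  $\Omega = 0$ recovers the independent-polygenic model.

### REML and the range parameter

Variance components maximize the restricted likelihood

$$\ell_R = -\tfrac12\left[\log|V| + \log(\mathbf 1^\top V^{-1}\mathbf 1) +
  y^\top P y + (n-1)\log 2\pi\right],$$

with $V = \sigma^2_g\Gamma + \Omega + \sigma^2_v I + \mathrm{diag}(se^2_i)$
as applicable and the intercept the only fixed effect.  Two routes are used:

* For the common two-component case $V = \sigma^2_g\Gamma + \sigma^2_e I$,
  $\Gamma$ is eigendecomposed once; in the rotated basis the likelihood is
  profiled analytically down to a one-dimensional search over the variance
  ratio.  This makes fits at $n$ = 1000–2000 routine.
* Models with fixed heterogeneous residuals or pedigree components use a
  dense-Cholesky likelihood with analytic gradients, optimized over
  log-variances (L-BFGS-B, with a derivative-free polish on small problems).

Boundary estimates are handled by explicit model reduction: a component is
set to exactly zero when refitting without it costs less than `1e-6`
log-likelihood units (the `boundary_tol` control).  Under a truly null
component this positive-part behaviour lands on the boundary roughly half to
two-thirds of the time — an estimate of exactly 0 is a legal and expected
outcome, mirroring the routinely-zero mother variances in multi-family
designs.

The kernel range $\theta$ is profiled by an outer one-dimensional search: a
log-spaced grid of effective ranges (13 points spanning 0.05 times the
median to 30 times the maximum pairwise distance, mapped into each kernel's
native parameterization), refined by golden section, with geometric extension
at either edge because two limits are genuine plateaus — $\theta \to \infty$
approaches the ridge/quadratic model (first-order Taylor:
$e^{-d^2/\theta^2} \approx 1 - d^2/\theta^2$) and $\theta \to 0$ the
independent model.  On heterozygote-free codes the connection is exact:
$ZZ^\top = m\mathbf{11}^\top - D^2/2$, so the quadratic kernel at
$\theta = 1/(2m)$ *is* ridge regression with $\sigma^2_g$ rescaled by $m$.

The linear, quadratic and spherical kernels need not yield a positive
semidefinite $\Gamma$; `stabilize_gamma()` clips negative eigenvalues at zero
by default (a diagonal-jitter alternative is available) and the correction is
recorded in the fit.

### Breeding values

GEBVs are BLUPs of $\mu + h_i$:
$\hat g = \hat\sigma^2_g \Gamma_{\mathrm{obs}} V^{-1}(y - \hat\mu\mathbf 1)$
for phenotyped individuals and
$\hat g_{\mathrm{new}} = \hat\sigma^2_g \Gamma_{\mathrm{new,obs}}
V^{-1}(y-\hat\mu\mathbf 1)$ through the cross-covariance block (marker
cross-products for RR, kernel values of cross-distances otherwise) for
unphenotyped ones.  The polygenic BLUP $\hat v$ is added only in fixed-
residual mode, where $v$ is genuinely genetic; in pooled mode the iid
component contains the residual error and contributes nothing to a breeding
value.  Independent polygenic effects contribute nothing out-of-sample
either, so unphenotyped predictions are driven by the markers — plus
predicted father/mother/cross effects (added whenever their variance
estimate is positive) when the pedigree model is on.

Model choice uses $\mathrm{AIC} = -2\ell_R + 2q$ with $q$ the number of free
covariance parameters, counting the profiled $\theta$ and counting
boundary-zero components (they were estimated), not counting the fixed
$se^2_i$.  Accuracy is summarized by Pearson correlations of GEBV with the
stage-1 fitted values (phenotyped set) and with true breeding values
(unphenotyped validation set) when a simulation supplies them.

## The synthetic-data generator

`sim_population()` emulates the structure of a workshop-style GS dataset and
is the package's test bed.  Defaults: 2 fathers crossed to 10 mothers, 100
offspring per cross (2000 offspring), 450 biallelic markers with founder
allele frequencies uniform on [0.2, 0.8], 30 QTL among the markers with
N(0, 1.5²) additive effects, half of the offspring phenotyped at times 0,
132, 265, 397, 530, prediction target time 600.  The growth baseline is
$\alpha = 100$, $\beta = 9$, $\gamma = 0.01$ — an S-curve whose inflection
(~t = 220) sits inside the measurement window — with the true breeding value
shifting the asymptote, $\alpha_i = \alpha + \mathrm{TBV}_i$, and
measurement error sd 1.  These defaults give var(TBV) in the tens, i.e. a
marker-dominated trait with small within-individual error, matching the
regime the method is designed for (fixing the residual variances then barely
changes anything, which the tests assert as a rank correlation above 0.99
between pooled- and fixed-mode GEBVs of the validation set).

Markers segregate independently by default; a `marker_spacing_cm` option
places them on a single chromosome with Haldane recombination.  Inheritance
is strictly additive.  What the generator does *not* emulate: a real
multi-chromosome genome, selection or non-random mating, dominance or
epistasis, genotyping error, and any particular real dataset's trait
architecture.  Passing tests on these populations therefore demonstrates the
estimator's correctness and calibration under its own assumptions, not
performance on real data.

### Monte-Carlo designs used in the test suite

Problem sizes in the tests are chosen to keep the suite fast while leaving
the checks sharp: oracle comparisons run at $n \le 30$ against dense
grid-plus-polish searches; equivalence checks (ridge vs quadratic, Gaussian
limit) at $n$ = 80–100; stage-1 calibration at 500 individuals (1000 pooled
df, 99% chi-square band, 90–99% empirical coverage of the 95% extrapolation
intervals); model-comparison patterns over 5 replicate populations of 240.
The variance-component recovery study uses $n$ = 300 with 100 markers at
0.5 cM spacing, true $\theta$ at 0.6 times the median pairwise distance and
$(\sigma^2_g, \sigma^2_v) = (4, 2)$: tight linkage widens the spread of
realized relatedness and the sub-median range places the correlation contrast
across that spread, which is where the data are informative about all three
parameters at once.  With independent markers the pairwise distances
concentrate in a narrow band (coefficient of variation $\propto 1/\sqrt m$)
and $\sigma^2_g$, $\sigma^2_v$ and $\theta$ become badly confounded — a
useful reminder that kernel GS on weakly structured panels estimates the
*predictions* far better than the *components*.

## Known limitations

* The pooled residual mode cannot separate polygenic variance from
  between-individual error — the two are reported as one component; only
  external replication (or the fixed within-individual variances of stage 1)
  gives partial separation.
* $\theta$ near its plateaus (ridge or independent limits) is weakly
  identified; the reported $\hat\theta$ can then be large and unstable even
  though the fit and the GEBVs are stable.
* Boundary frequencies for truly-null components follow positive-part REML
  behaviour (roughly half to two-thirds at zero in the designs examined), so
  a single dataset's zero estimate should not be over-interpreted.
* No multi-generation kinship: the pedigree model covers father, mother and
  cross indicators only, which is the appropriate structure when parents are
  themselves unrelated and un-genotyped.
* No cross-validation engine and no smoothing-based model-selection criteria;
  model choice rests on AIC and, in simulations, on validation-set accuracy.
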