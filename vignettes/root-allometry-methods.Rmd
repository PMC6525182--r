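---
title: "Allometric root anatomy and nonlinear trait relationships: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric root anatomy and nonlinear trait relationships: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootAllometry)
```

## The geometric model

An absorptive root is treated as a cylinder of diameter $x$ (mm) built from
two concentric tissue classes: a central stele of radius $SR$ and the tissues
outside the stele (epidermis, exodermis, cortex) of combined thickness
$tToS$, so that $SR + tToS = x/2$. Anatomical surveys find that $tToS$ grows
linearly but allometrically with diameter,

$$tToS = k\,x + c, \qquad 0 < k < 1/2,$$

which forces the stele radius onto the complementary line
$SR = (1/2 - k)\,x - c$ and makes the proportion of cross-sectional area
occupied by the stele

$$PRS = \left(\frac{2\,SR}{x}\right)^2 = \left(1 - 2k - \frac{2c}{x}\right)^2$$

a *nonlinear* function of diameter. The sign of the intercept $c$ decides the
direction: $c < 0$ (the woody pattern) makes PRS fall with diameter, $c > 0$
(the non-woody pattern) makes it rise. `prsFromDiameter()` evaluates this
curve and *flags* diameters where the inner term leaves $[0, 1]$ — the
geometry there is unrealizable and clipping it would fabricate curvature, so
such points are returned as `NA` and excluded from downstream fits.

Because stele tissue is lignified vascular tissue it is denser and poorer in
nitrogen than the cortex. Whole-root tissue density (RTD, g cm$^{-3}$) and
nitrogen concentration (RN, mg g$^{-1}$) are modelled as area-weighted
mixtures, `mixtureTrait(PRS, vStele, vOuter)`, which transmits the PRS
nonlinearity to the measurable traits: RTD inherits a falling, convex
diameter relationship in the woody case and RN a rising one. The trait curves
are fitted in the allometry-derived form

$$y = (a + b/x)^2 + d,$$

by `nlsAllometricFit()`. Two auxiliary identities close the system: specific
root length $SRL = 4 / (\pi \cdot RTD \cdot x^2)$ (`srl()`, diameters held in
mm throughout the data model and converted to cm only inside this function
and `dryMassPerLength()`), and dry mass per length
$m(x) = \pi (x/2)^2 \, RTD(x)$.

### Dry-mass monotonicity is provable, not merely simulated

On the valid PRS domain,
$m(x) \propto \rho_c x^2 + (\rho_s - \rho_c)\,((1-2k)x - 2c)^2$ with
$(1-2k)x - 2c \in (0, x)$, so $m'(x) > 0$ for any stele density
$\rho_s > \rho_c \ge 0$: the $x^2$ volume term always outruns the falling
tissue density. `dryMassMonotonicity()` therefore reports, rather than
asserts, monotonicity — and within the two-tissue model no parameter choice
can break it (a 2000-configuration random search confirms the algebra). The
practical reading: diameter, not tissue density, controls the dry-mass cost
of building an absorptive root.

## Estimation machinery

* **OLS** (`olsFit()`) is the closed-form normal-equation solution with
  two-sided $t$ tests; it is written out rather than delegated so the
  pipeline's core estimator is self-contained and testable against `lm()`.
* **Allometric NLS** (`nlsAllometricFit()`) is Levenberg-Marquardt with the
  analytic Jacobian of $(a + b/x)^2 + d$, eight starts spanning the sign and
  scale of $b$, convergence at relative SS change $< 10^{-10}$, at most 500
  iterations. The curve is invariant under $(a, b) \to (-a, -b)$, so $a \ge 0$
  is enforced and the sign of $b$ carries the direction of the relationship
  (it mirrors the sign of $c$). A constant response returns a flagged
  degenerate fit with $d = \bar y$. An `anchored` mode fixes the curve shape
  at externally fitted $(k, c)$ and estimates only the affine trait map on
  the PRS regressor; the free mode is the default since the original analyses
  do not state that their trait fits were anchored.
* **SMA** (`smaFit()`): slope $= \operatorname{sign}(r)\,s_y/s_x$, the
  standard likelihood CI, and a common-slope likelihood-ratio test
  (`smaCommonSlopeTest()`) using the Warton-Weber modified statistic
  $-\sum_i (n_i - 2.5)\log(1 - r_i^2(\hat b))$ against $\chi^2_{g-1}$, with a
  seeded label-permutation reference (999+ draws) whenever any group has
  $n < 20$.
* **Outlier rule** (`excludeOutliers()`): records beyond 4 interquartile
  ranges from the median of RN or of PRS are removed before the PRS-stage
  fits, every exclusion logged with species and reason. On the synthetic
  data the heavy right tail of PRS at the thinnest diameters means a handful
  of genuine records can exceed this distance; they are logged like any
  other exclusion, which is the rule working as specified.

## Phylogenetic comparative statistics

All comparative statistics are computed from the Brownian-motion covariance
$C$ ( `vcvMatrix()`: $C_{ij}$ = shared root-to-MRCA path length), built by a
single postorder pass. Trees read from Newick must carry branch lengths;
polytomies are resolved (`resolvePolytomies()`) into seeded random
bifurcations with zero-length inserted edges, and a $10^{-8}$ branch-length
floor is applied before any matrix inversion so those edges cannot make $C$
singular.

* **PIC** (`picContrasts()`): Felsenstein pruning — contrast
  $(v_i - v_j)/\sqrt{b_i + b_j}$, weighted ancestral value, parent branch
  extended by $b_i b_j/(b_i+b_j)$. `picRegression()` orients each contrast
  pair so the $x$-contrast is positive and regresses through the origin; its
  slope equals the BM-PGLS slope exactly, a property the tests exercise on
  random trees.
* **Blomberg's K** (`blombergK()`): observed MSE$_0$/MSE against its BM
  expectation, so K calibrates to 1 under Brownian motion. Significance is a
  seeded tip-shuffle permutation test (999 draws by default; the original
  analyses do not state their scheme, so this common choice is ours and is
  labelled in the output).
* **Pagel's λ** (`pagelLambdaML()`): the transform multiplies off-diagonal
  entries of $C$ by λ and leaves the diagonal untouched (stated explicitly
  because definitions vary off the ultrametric case). The mean and rate are
  profiled analytically; λ is maximized on $[0,1]$ by bounded scalar search
  (tolerance $10^{-6}$) with both endpoints checked; the reported $p$ is the
  LR test against λ = 0 on 1 df. Star trees are rejected as unidentifiable.
* **PGLS** (`pglsFit()`): $\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$
  with formula-based designs, so interaction terms (diameter × growth form,
  diameter × mycorrhizal type) expand through `model.matrix`; rank
  deficiency errors name the collinear columns. `correlation = "lambda"`
  rescales $C$ at the response's ML λ first.

Calibration checks run in the test suite: mean K over 200 BM simulations on
100-tip trees lies in $[0.9, 1.1]$; λ is recovered with mean absolute error
$\le 0.1$ at 300 tips for true λ ∈ {0, 0.5, 1}; PIC and PGLS slopes agree to
$10^{-8}$ on 100 random trees. The problem sizes were chosen to make these
Monte-Carlo calibrations tight while keeping the default suite quick to run.

## The synthetic-data generator

`generateDataset()` emulates the statistical structure of a global
absorptive-root trait compilation so that every analysis stage runs, and can
be scored against known truths, without any external data. Defaults are the
study conditions:

| quantity | default | provenance |
|---|---|---|
| woody tToS line | $k = 0.43$, $c = -0.016$ mm | published woody regression |
| non-woody tToS line | $k = 0.32$, $c = 0.011$ mm | published non-woody regression |
| woody SR line (independent mode) | slope 0.068, intercept 0.016 mm | published slope; intercept is the geometric complement of $c$ (not printed in the source) |
| group sizes | 505 woody / 361 non-woody | published species counts |
| woody mycorrhizal mix | AM 376, EM 89, ERM 13, NM 3, AM+EM 17, unknown 7 | published counts |
| anatomy subset | 158 woody, 13 non-woody species | published anatomy coverage |
| noise sds | $\sigma_t = 0.02$ mm, $\sigma_{SR} = 0.004$ mm, $\sigma_{RTD} = 0.05$, $\sigma_{RN} = 2$ | free parameters; no noise magnitudes are published |
| diameters | lognormal, woody median 0.35 mm (sdlog 0.45), non-woody 0.25 mm (sdlog 0.4) | chosen to span 0.1–1.2 mm |
| tissue mixture | $\rho_s = 0.45$, $\rho_c = 0.12$ g cm$^{-3}$; $\nu_s = 6$, $\nu_c = 14$ mg g$^{-1}$ | generator conveniences, not estimates |
| diameter phylogenetic signal | λ = 0.83, $\sigma^2 = 1$ | the published woody diameter λ |

Mechanics: a Yule tree is simulated over all species; a latent trait evolves
on it by Brownian motion with the configured λ; within each growth form the
latent values are mapped rank-preservingly onto the lognormal diameter
marginal (a copula-style map, so the marginal is exact and phylogenetic
signal survives); tToS follows its line plus Gaussian noise; SR is either the
exact cylinder complement ("complement" mode, the non-woody default) or its
own noisy regression line ("independent" mode, the woody default — the
published woody SR slope 0.068 is not the exact complement $0.5 - 0.43$, and
independent noise reproduces that); PRS comes from the anatomy; RTD and RN
are tissue mixtures plus noise; SRL follows the cylinder identity. All
randomness derives from one mandatory master seed through named per-stage
substreams, so a config plus seed fixes every output byte.

Two boundary rules deserve explanation. First, $\sigma_t = 0.02$ mm is large
relative to the *non-woody* stele ($SR \approx 0.034$ mm at the median
diameter), so a few percent of complement-mode noise draws push $SR$ below
zero; those records are flagged as missing anatomy rather than failing the
run, while stele proportions *above one* (stele wider than the root) remain a
hard configuration error above a 1% frequency. Second, `injectOutliers()`
caps inflated PRS at 1 and marks every injected record in an
`outlier_injected` truth column so the exclusion rule can be scored.

`makeDataSourceClasses()` implements the sampling-bias mechanism that
reconciles conflicting literature correlations: on the woody curve the steep
region is the thin-diameter, high-RTD region, so the "correlated" study
class is drawn to contain thin-pool records (thinnest 35% of diameters) at
53% frequency versus 17% in the "uncorrelated" class. Selection is on
*diameter*, not on measured RTD: selecting on the noisy response would
itself distort the within-class correlations being compared. A consequence
worth stating plainly: with the default $\sigma_{RTD} = 0.05$ the woody
diameter-RTD $R^2$ is only ≈ 0.05–0.1 (the published analysis reports 0.36),
so the class-level $R^2$ ordering holds in expectation and in the clear
majority of seeds but not on every seed; the mechanism is deterministic, the
measurement noise is not.

### What the generator does and does not emulate

It reproduces: lognormal diameter spreads per growth form, the linear
anatomy allometries with the published slopes and intercept signs, the
geometric SR complement, mixture-driven positive PRS-RTD and negative PRS-RN
associations, phylogenetic signal in diameter, grouping vocabularies and
sample sizes, duplicate study records, and the thin-root sampling bias. It
does **not** emulate: measurement-method heterogeneity across literature
sources, the real (non-Yule) shape of the vascular-plant phylogeny,
covariation between mycorrhizal type and the trait curves (group labels are
assigned independently of the traits, so group-difference tests on default
output are null cases), climatic structure, or realistic RTD spans — the
two-tissue mixture with observed PRS ≤ 0.2 compresses RTD into ≈ 0.1–0.2
g cm$^{-3}$. Passing tests therefore certify the machinery and its
statistical calibration, not ecological conclusions about real roots.

## Group analyses and the design substitution

`fitByGroup()` fits the allometric curve per factor level, skipping levels
with fewer than 10 records (mirroring analyses restricted to the main
mycorrhizal types). `interactionTest()` compares `y ~ x + factor` against
`y ~ x * factor` by an OLS ANCOVA $F$ test. The original analysis used a
REML linear mixed model with study structure here; the interaction $p$ value
is the only downstream quantity, an OLS ANCOVA reproduces it qualitatively,
and a from-scratch REML implementation would be out of proportion to its
role — so the substitution was made deliberately and every report carries a
`substitution_note` saying so. Record conservation (rows in = rows out +
rows excluded) is asserted at each exclusion stage.

## Pipeline and reproducibility

`simulateToFiles()` writes `traits.csv`, `tree.nwk`, `truth.json` and a
manifest with md5 hashes; `analyzeFiles()` runs the stages in the order
anatomy allometry → SMA comparisons → PRS stage → nonlinear trait fits →
interaction tests → phylogenetic stages → data-source split, skipping (with
a logged reason) phylogenetic stages without a usable tree and the
data-source stage without assigned classes; `recoverySummary()` repeats
simulate-and-fit and reports bias and CI coverage; `validateReport()` checks
reports against the JSON schema shipped in `inst/schema/`. A thin command
line (`inst/scripts/root-allometry.R`) exposes `simulate`, `analyze`,
`recover` and `report` subcommands over these functions.

## Known limitations

* The exact fitted trait-regression equations from real datasets are not
  transcribed anywhere in this package; the tissue mixture is a faithful
  mechanism, not a transcription, so synthetic trait-curve $R^2$ values are
  not comparable to published ones and no test asserts them.
* λ estimation is bounded to $[0, 1]$; data preferring λ > 1 sit at the
  boundary.
* The SMA module covers slope estimation and the common-slope test only; no
  elevation or shift tests.
* The OLS ANCOVA substitution ignores study-level pseudo-replication; its
  $p$ values are anti-conservative when study effects are strong.
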