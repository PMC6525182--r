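# rootAllometry

Absorptive roots — the most distal, ephemeral root orders that do a plant's
nutrient and water foraging — are often analyzed under the *root economics
spectrum* (RES), which predicts linear acquisition–conservation tradeoffs
between root diameter, root tissue density (RTD, g cm⁻³) and root nitrogen
concentration (RN, mg g⁻¹). `rootAllometry` implements the competing
allometric view: a root is a cylinder of two concentric tissues, the stele
(radius SR) and the tissues outside the stele (thickness tToS), with

```
tToS = k·x + c            (x = root diameter, mm;  0 < k < 1/2)
```

so the proportion of cross-sectional area occupied by the stele is the
nonlinear curve

```
PRS = (2·SR / x)² = (1 − 2k − 2c/x)²
```

Because the stele is denser and N-poorer than the cortex, whole-root RTD and
RN are area-weighted tissue mixtures driven by PRS — making their diameter
relationships intrinsically nonlinear, of the form `y = (a + b/x)² + d`, with
the sign of `c` setting the direction (negative: woody, PRS falls with
diameter; positive: non-woody, PRS rises). The package provides, as one
tested pipeline:

* the geometric model and derived quantities (PRS, SRL = 4/(π·RTD·x²), dry
  mass per length, dry-mass monotonicity reports);
* closed-form OLS, allometry-form nonlinear least squares
  (Levenberg–Marquardt, multi-start, analytic Jacobian), and standardized
  major axis slopes with a common-slope likelihood-ratio test;
* from-scratch phylogenetic comparative statistics: independent contrasts,
  Blomberg's K (permutation test), maximum-likelihood Pagel's λ (LR test),
  and PGLS with interaction designs, all built on a Brownian-motion
  covariance computed from the tree;
* group analyses: per-mycorrhizal-type curve fits, ANCOVA interaction tests,
  the data-source split with the high-RTD frequency comparison, and the
  4-IQR outlier rule with a full exclusion log;
* a synthetic trait-and-tree generator whose defaults reproduce the study
  conditions (505 woody / 361 non-woody species, the published allometry
  parameters, mycorrhizal composition, anatomy coverage), so every stage
  runs and can be scored against known truths with no external data.

It is aimed at root-trait and phylogenetic comparative method users who want
the allometric analysis chain reusable, seeded, and testable.

## Worked example

```r
library(rootAllometry)

cfg <- generatorConfig(seed = 2026)      # defaults = the study conditions
dat <- generateDataset(cfg)
dat
#> RootTraitData: 866 records, 866 species, tree with 866 tips
#> non-woody     woody
#>       361       505

tab <- traits(dat)
w <- tab[tab$growth_form == "woody" & is.finite(tab$tToS), ]
fit <- fitAnatomyAllometry(w$diameter, w$tToS)
fit$params
#> AllometryParams: tToS = k*x + c with k = 0.4261503 , c = -0.01353351 mm
#>   implied stele-radius slope 0.5 - k = 0.07384967
fit$fit
#> LinearFit (n = 158): y = 0.42615 x + -0.0135335
#>   slope SE 0.00877, p = 3.99e-96, R^2 = 0.9380

prsFromDiameter(c(0.2, 0.5, 1.0), fit$params)
#> [1] 0.08010849 0.04073671 0.03054328
```

The 158 woody species carrying anatomy recover the generating line
(truth k = 0.43, c = −0.016) within one standard error, and the fitted
parameters predict a *decreasing* stele proportion — 8% of cross-section at
0.2 mm down to 3% at 1 mm — which is what the negative intercept encodes.
The nonlinear trait fit across all woody species,

```r
i <- tab$growth_form == "woody"
nlsAllometricFit(tab$diameter[i], tab$RTD[i])
#> NonlinearFit (n = 505): y = (0.173261 + 0.0171023/x)^2 + 0.0900859
#>   R^2 = 0.0624, converged = TRUE (6 iterations)
```

shows the falling convex RTD–diameter curve (positive `b` with `a ≥ 0`); its
modest R² reflects the generator's default measurement noise, which dominates
the mixture signal (see the methods vignette).

End-to-end, with files:

```r
simulateToFiles(cfg, "out")                          # traits.csv, tree.nwk, truth.json, manifest.json
analyzeFiles("out/traits.csv", "out/tree.nwk", "out/analysis")
```

writes `out/analysis/report.json` with every stage — anatomy allometries and
SMA slope comparisons, the PRS stage with its exclusion log, nonlinear fits
by growth form / mycorrhizal type / root order, interaction tests,
phylogenetic signals (K, λ) and PGLS, and the data-source split. The same
operations are available from a shell via
`Rscript inst/scripts/root-allometry.R {simulate|analyze|recover|report}`.

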