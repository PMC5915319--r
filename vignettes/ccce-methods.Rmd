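---
title: "Detecting common-environment effects on immune cell subfunctions"
author: "ccce package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting common-environment effects on immune cell subfunctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccce)
```

## The problem

Multicolor flow cytometry measures, for one isolated cell type, the surface
level of a panel of $k$ marker proteins on every cell. Discretizing each
marker as present (`+`) or absent (`-`) partitions the cells into up to $2^k$
*subpopulations*; the fraction of cells falling into each subpopulation — the
cell subpopulation frequency (CSF) — is one quantitative trait per
subpopulation per individual. Each marker also defines a *subfunction*: the
functionality that the protein confers on the cell type regardless of which
other markers accompany it (for example, surface Thrombomodulin gives
monocytes an anticoagulant subfunction).

When such traits are measured across a cohort of monozygotic (MZ) and
dizygotic (DZ) twin pairs, the trait variance can be split into
additive-genetic ($h^2$), common/family-environment ($c^2$) and unique
($e^2$) components. The scientific question this package addresses is: *does
the common environment act on a subfunction* — i.e., coherently on all
subpopulations carrying a marker — rather than on one particular
subpopulation? Asking the question marker-by-marker on single-marker
frequencies is confounded by subpopulation composition: one abundant
subpopulation that happens to carry a marker can masquerade as a subfunction
effect. The method regresses the per-subpopulation $c^2$ jointly on all $k$
marker indicators, so that every subpopulation contributes equal evidence and
composition bias is removed.

## The model and the procedure

**Variance decomposition.** For each CSF trait, a pooled ordinary
least-squares fit of trait on age is computed first and the trait replaced by
its residuals (plus the trait mean, to stay on the percent scale): age is a
known confounder of immune traits and of the shared environment of twins.
The twin correlations $r_{mz}$ and $r_{dz}$ are then computed by
*double-entry* Pearson correlation — each complete pair $(a, b)$ contributes
both $(a, b)$ and $(b, a)$ — which removes the arbitrary labelling of twin 1
versus twin 2 and equals the moment intraclass correlation in expectation.
The Falconer moment estimator gives

$$h^2 = 2\,(r_{mz} - r_{dz}), \qquad c^2 = 2\,r_{dz} - r_{mz}, \qquad
  e^2 = V_p - h^2 - c^2 .$$

By default each age-adjusted trait is standardized to unit variance
($V_p = 1$), so the components are fractions and $c^2$ is directly the
regression target. Raw estimates can be negative — they are moment
estimators — and are reported as such; `clamp = TRUE` truncates at zero and
renormalizes for users who need components in $[0, V_p]$, at the cost of
masking estimation noise.

**Quality control.** A trait is *high-quality* when its replicate
correlation exceeds 0.3 (strictly) and its mean lies between 1% and 99%
(inclusive; the bounds exclude subpopulations too rare or too saturated for
the frequency to be informative). A dataset (one cell type, one panel) is
analyzable when at least 18 high-quality traits remain. Traits lacking a
replicate measurement pass the replicate criterion only when the filter is
explicitly relaxed (`require_replicate = FALSE`).

**The subfunction regression.** The kept subpopulations form the rows of a
$\pm 1$ design matrix $X$ (one column per marker, $+1$ = present), and the
model is the elastic net

$$\min_{\beta_0,\beta}\; \tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
  + \lambda\left(\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),$$

with $y$ the $c^2$ vector, the intercept unpenalized, and the predictors
deliberately *not* re-standardized: a balanced two-level $\pm 1$ code is
already on a common scale, and raw coding keeps the coefficients
interpretable as presence-versus-absence contrasts. Regularization guards
against overfitting with as few as 18 observations and up to 8 markers.

**Tuning.** $(\lambda, \alpha)$ are chosen by $K$-fold cross-validation with
$K = \lfloor n/5 \rfloor$ (floored, never below 2): many folds while keeping
at least five subpopulations per fold. One seeded fold partition is shared
across the entire grid, so grid points are compared on identical splits and
fold noise cannot masquerade as a tuning signal. The default grid is 20
log-spaced penalties in $[10^{-3}, 10]$ crossed with mixing weights
$\{0.1, 0.5, 0.9, 1\}$ — ridge-like through lasso. Exact ties are broken
toward the larger penalty, then the larger mixing weight, i.e. the sparser
model. The selected model's cross-validated prediction error (mean held-out
squared error over folds) is the test statistic.

**Significance.** The permutation null shuffles $y$ across subpopulations —
the most conservative permutation, breaking any tie between $c^2$ and the
signatures while preserving the internal structure of each — and reruns the
*full* selection procedure, grid search included, on every shuffle (1000 by
default). Each permutation replicate draws a fresh fold partition from its
own derived seed; re-using one partition across all shuffles would be an
equally defensible design, but refreshing makes the null distribution
reflect fold variability as well as shuffle variability. The p-value is the +1-corrected
empirical tail,
$p = \bigl(1 + \#\{\text{perm error} \le \text{observed error}\}\bigr) /
(n_{\text{perm}} + 1)$, which cannot reach zero and is conservative. Across
cell-type datasets, Benjamini–Hochberg step-up q-values control the FDR (the
discovery threshold used downstream is $q < 0.1$).

**Leading subfunction.** The marker with the largest $|\hat\beta_j|$ is
reported with its sign: positive links marker *presence* with the common
environmental effect, negative links its *absence*. Exact ties report all
tied markers; an all-zero fit reports an explicit "none" sentinel rather
than an arbitrary marker.

## The solver

The elastic net is solved by cyclic coordinate descent with warm starts along
a decreasing penalty path (implemented in C++; the permutation test re-runs
the grid search a thousand times per dataset, so the inner solver is the hot
loop). Soft-threshold updates use the standard closed form; convergence is
declared when the largest parameter change in a sweep falls below `tol`
(default $10^{-9}$). The test suite pins the solver against two independent
references: a pure-R coordinate descent that eliminates the intercept by
centering (a different formulation of the same optimum), and, on
full-factorial designs where $X^\top X = nI$, the exact closed form
$\hat\beta_j = S(\tfrac{1}{n} x_j^\top (y - \bar y),\, \lambda\alpha) /
(1 + \lambda(1-\alpha))$; the lasso path is additionally checked against
glmnet. A constant training response degenerates gracefully to the
intercept-only fit (relevant for permutation replicates of a near-constant
$c^2$ vector).

## The simulator

`plant_effects()` + `simulate_cohort()` generate the ground truth used by
every statistical test in the package. The planted model is exactly the
assumption the regression encodes: $c^2_s = \mathrm{clip}(c_0 + x_s^\top\beta
+ \eta_s,\ 0.02,\ 0.9)$ per subpopulation $s$, with clip bounds keeping all
three components strictly positive; $h^2_s$ is uniform on $[0.1, 0.6]$
subject to $h^2_s + c^2_s \le 0.95$ (or fixed by the caller), and
$e^2_s = 1 - h^2_s - c^2_s$. Twin structure follows the additive model: the
genetic component is identical within MZ pairs and correlated exactly 0.5
within DZ pairs (shared + unique split), the common component is identical
within every pair, the unique component independent; ages are uniform on
[20, 70], shared within a pair, and enter the liability linearly (default
slope 0.01/year, a modest confound the age adjustment must remove).

Liabilities map to the percent scale through
$100 \cdot \mathrm{logit}^{-1}(b_s + 0.5\,\ell)$ with subpopulation-specific
baselines $b_s \sim U(-1.5, 1.5)$, giving mean frequencies in roughly
12–82% (inside the QC window) and a mild monotone nonlinearity that
attenuates twin correlations slightly — which is why estimator-recovery
studies run on the pre-mapping liability scale while end-to-end power
studies run on the percent scale, honestly documenting the attenuation.
Replicates add independent liability-scale noise calibrated to a replicate
correlation of about 0.9, comfortably above the 0.3 QC threshold.

What the simulator does *not* emulate: multinomial cell-counting noise (the
$2^k$ frequencies of an individual are generated independently and do not
sum to 100%), cytometry spillover/compensation artifacts, non-additive
genetics, and sex effects (the large public twin immunophenotype cohorts
this method targets are all-female registries). Passing
tests therefore demonstrate correctness of the estimator and calibration of
the permutation test under the additive ACE model with a linear
subfunction effect — not robustness to those unmodelled features.

## Study conditions used by the validation suite

The statistical acceptance checks (also recomputed by
`scripts/acceptance.R`) run at these problem sizes, chosen to match the
regime the method targets:

* **Null calibration** — 500 null datasets, $k = 5$ with 24 retained traits,
  99 permutations each: the fraction of $p \le 0.05$ must sit inside the
  binomial 99% interval [0.027, 0.078]. Under exchangeable $y$ the
  permutation test is exact, so this checks the implementation, not the
  theory.
* **Power and leading-subfunction recovery** — 50 cohorts of 250 MZ + 250 DZ
  pairs, $\beta = 0.2$ planted on one of five markers (rotating), baseline
  $c_0 = 0.3$, c²-noise 0.05, 199 permutations: at least 90% of runs must
  reach $p \le 0.05$ with the correct leading marker. (The permutation count
  is scaled down from the reference 1000 to keep the suite fast; the p-value
  floor $1/(n_{perm}+1)$ is far below the 0.05 criterion either way.)
* **Falconer recovery** — 200 cohorts of 500 + 500 pairs with
  $(h^2, c^2, e^2) = (0.4, 0.3, 0.3)$ planted on all 8 subpopulations of a
  $k = 3$ panel, liability scale: the cohort-level estimate of each component
  (the mean across the cohort's traits, the natural estimator of a value
  shared by construction) must land within $\pm 0.08$ of truth in at least
  95% of cohorts. A *single-trait* Falconer estimate at this cohort size has
  a sampling standard deviation of about 0.08 for $h^2$
  ($\mathrm{sd} \approx 2\sqrt{\mathrm{var}(r_{mz}) + \mathrm{var}(r_{dz})}$),
  so per-trait estimates cannot meet such a band with 95% coverage — no
  estimator could; averaging the 8 independent trait estimates divides the
  sd by $\sqrt{8}$ and makes the check a meaningful test of unbiasedness.

## Numerical and design choices

* **Seeds.** Every stochastic step (fold shuffles, permutations, simulator
  draws) takes an explicit seed; child seeds are derived deterministically
  from the master seed, so permutation replicates can run in parallel with
  results identical to sequential execution.
* **Degenerate inputs.** All-identical ages make the age adjustment
  unidentifiable (error, not silent pass-through); zero-variance traits and
  fewer than two complete pairs are errors naming the trait/zygosity;
  constant responses yield a p-value of exactly 1.
* **Label dialect.** Subpopulation labels are marker symbols each followed
  by `+`/`-` (Unicode minus accepted on input, ASCII emitted), any order,
  every panel marker exactly once; unknown or missing markers are parse
  errors, never silently ignored — a silently mis-parsed label would corrupt
  the design matrix.
* **Canonical enumeration order** is lexicographic over the sign vector with
  `+` before `-`, making all outputs byte-reproducible.
* **Missing data** are handled per trait: an individual missing a value (or
  an age) is dropped for that trait only, and a pair with a missing member
  is excluded from that trait's correlation entirely.
* **Precomputed c² bypass:** a `subpopulation → c2` table can replace the
  twin-variance stage entirely, for cohorts where the decomposition was done
  elsewhere.
* **Interface.** The R functions are the primary interface;
  `inst/cli/ccce.R` wraps them as `run` / `falconer` / `simulate` /
  `validate` subcommands for shell pipelines.

## Limitations

The Falconer estimator assumes the additive ACE model (no dominance, no
gene–environment interaction, equal environments across zygosities); its
per-trait estimates are noisy at realistic cohort sizes, and the regression
inherits that noise as response error. The permutation test is exact only
under exchangeability of the $c^2$ estimates across subpopulations —
estimates from the same individuals are correlated across traits, which the
shuffle preserves only partially; the calibration study above shows the
test holds its level under the simulator's conditions. Main effects only:
interactions between markers are deliberately out of scope.

```{r session}
sessionInfo()
```
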