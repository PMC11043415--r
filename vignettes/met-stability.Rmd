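---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Plant breeders evaluate candidate genotypes in multi-environment trials
(MET): the same set of genotypes grown in replicated designs at many
locations. Mean yield alone is a poor selection criterion because the
genotype-by-environment (G×E) interaction reshuffles rankings between
locations; a cultivar recommendation needs both *performance* and
*stability*. `metstab` implements the standard analysis chain for a
balanced MET laid out as a randomized complete block design (RCBD) within
each environment: combined ANOVA and heritability, the AMMI model, six
univariate stability statistics, and GGE-biplot geometry. The packaged
worked example is a 20-genotype × 12-location × 3-replicate rice
(paddy-yield) trial, available as `gsr_yield_means()`.

## Combined ANOVA and genetic components

The observation model is

$$y_{ijr} = \mu + E_j + R_{r(j)} + G_i + (GE)_{ij} + \varepsilon_{ijr},$$

with replicates (blocks) *nested within* environments. For $g$ genotypes,
$q$ environments and $r$ replicates the degrees of freedom are $q-1$,
$q(r-1)$, $g-1$, $(g-1)(q-1)$ and $q(g-1)(r-1)$. The environment main
effect is tested against the block stratum REP(ENV); everything else
against the pooled error. We deliberately model replication as nested
(rather than a crossed "replications" term with $r-1$ df) because only the
nested layout makes the error df of a trial of this shape internally
consistent ($456$ at $20 \times 12 \times 3$).

From the genotype and error mean squares, `genetic_components()` computes

$$\hat\sigma^2_g = \frac{GMS - EMS}{r}, \qquad
  \hat\sigma^2_e = \frac{EMS}{r}, \qquad
  \hat\sigma^2_p = \hat\sigma^2_g + \hat\sigma^2_e, \qquad
  h^2_B = 100\,\frac{\hat\sigma^2_g}{\hat\sigma^2_p}.$$

Note the divisor: $r$ alone, *not* the textbook across-environment
$r\,q$. Trial reports in this tradition quote "genotypic variance" on
that scale (it equals $q$ times the variance of true genotype means), and
the packaged trial's published variance-component table is reproduced
exactly by the divisor-$r$ form. The textbook scaling is available with
`divisor = "rq"`. Negative $\hat\sigma^2_g$ (when $GMS < EMS$) is
reported as-is with a flag — clamping to zero would hide estimation
noise.

```{r genetics}
ms <- gsr_mean_squares()
gms <- unlist(ms[ms$source == "GEN", -(1:2)])
ems <- unlist(ms[ms$source == "ERROR", -(1:2)])
genetic_components(gms, ems, r = 3)
```

## The AMMI model

`ammi_fit()` decomposes the cell-means matrix as

$$\bar X_{ij} = \mu + \alpha_i + \beta_j +
  \sum_{k=1}^{K} \lambda_k \gamma_{ik} \delta_{jk},$$

additive main effects by marginal means plus an SVD of the
doubly-centered interaction matrix
$Z_{ij} = \bar X_{ij} - \bar X_{i.} - \bar X_{.j} + \bar X_{..}$, with all
$K = \min(g-1, q-1)$ axes retained so the reconstruction is exact. Axis
$k$ explains $EP_k = 100\,\lambda_k^2 / \sum_m \lambda_m^2$ percent of the
interaction sum of squares. Fitting on cell means loses nothing relative
to replicate-level data: the axis shares are identical, and
`ammi_anova()` recovers the observation-scale sums of squares as
$r\lambda_k^2$, assigns Gollob degrees of freedom $g + q - 1 - 2k$, and
tests each axis against the pooled error mean square of the combined
ANOVA. No Cornelius/FR tests are provided; the Gollob F-test is the
convention the packaged trial's report uses.

Numerical choices worth stating:

* **Score scaling.** Genotype and environment scores default to the
  symmetric $\gamma_{ik}\sqrt{\lambda_k}$ convention; raw eigenvectors
  and full-$\lambda$ scalings are options in `ammi_scores()`. The
  symmetric convention is what the downstream stability statistics
  assume.
* **Sign convention.** SVD signs are arbitrary, so each axis pair is
  flipped to make the largest-magnitude genotype score positive. This
  makes outputs bit-reproducible; every statistic downstream is invariant
  to the choice.
* **Rank deficiency.** Singular values beyond $K$ are numerically zero by
  construction and are excluded from the $EP$ normalization, so
  $\sum EP_k = 100$ holds exactly.

## Univariate stability statistics

All six statistics operate on the symmetric-scaled scores $s_{ik}$ or
directly on the cell means; lower values mean more stable, and
`stability_table()` assembles them with average-rank ties:

* **ASV** $= \sqrt{((SS_1/SS_2)\,s_{i1})^2 + s_{i2}^2}$ with
  $SS_k = \lambda_k^2$;
* **ASI** $= \sqrt{(s_{i1}\theta_1^2)^2 + (s_{i2}\theta_2^2)^2}$ with
  $\theta_k^2 = EP_k/100$;
* **joint-regression slope** $b_i$ of the genotype's environment means on
  the environmental index $I_j = \bar X_{.j} - \bar X_{..}$ (the slopes
  average exactly 1);
* **Wricke's ecovalence** $W_i^2 = \sum_j Z_{ij}^2$, the genotype's share
  of the interaction SS ($\sum_i W_i^2 = \sum_k \lambda_k^2$);
* **Shukla's stability variance**, the stated affine transform of
  $W_i^2$ (so its ranking equals the ecovalence ranking);
* **WAAS** $= \sum_k |s_{ik}| EP_k / \sum_k EP_k$, by default over all
  axes since the axis count behind published tables is rarely stated; the
  count is a parameter (`axes`), including `"significant"`.

Two caveats, both visible in the packaged published table
(`gsr_stability_published()`). First, its ASV and ASI columns are
*swapped* relative to the defining equations: recomputing both statistics
under the $\sqrt\lambda$ convention reproduces the printed ASI column
with the ASV equation and the printed ASV column with the
$\theta^2$-weighted ASI equation, consistently across all 20 genotypes.
`metstab` names the statistics by their equations and documents the swap
rather than perpetuating it. Second, the published WAAS column was
produced with BLUP-shrunken interaction effects (a mixed-model variant);
`waas()` is the fixed-effects version computed from the AMMI scores and
intentionally does not reproduce those shrunken values.

The blended WAASY score min–max rescales pooled yield (higher is better)
and WAAS (lower is better) to 0–100 and mixes them with a user weight;
weight 100 reproduces the yield ranking and weight 0 the stability
ranking. Quadrant classes come from (mean above/below the grand mean) ×
(WAAS below/above the median).

## GGE biplot geometry

`gge_fit()` centers each environment column ($Y_{ij} = \bar X_{ij} -
\bar X_{.j}$), keeping genotype main effect plus interaction (G+GE), and
decomposes $Y$ by SVD. No scaling by environment standard deviations is
applied — the packaged trial's reported axis percentages are consistent
with unscaled centering. Coordinates for the first two axes follow a
singular-value partitioning mode (symmetric $\sqrt\lambda$ by default;
genotype- or environment-metric as options); the rank-2 product
$G E^\top$ is identical under all three, which the tests assert.

The biplot analyses are returned as *data*, not drawings:

* `which_won_where()`: convex hull of the genotype points, sector
  boundary rays from the origin perpendicular to each hull edge,
  environments assigned to sectors by angle, and the winning vertex per
  sector. An environment exactly on a boundary goes to the
  counter-clockwise sector — a documented tie rule; ties occur with
  probability zero for measured data. Because the genotype points are
  centered (column centering puts their centroid at the origin), the
  origin lies inside the hull and the construction is well defined;
  collinear genotype points are reported as degenerate rather than
  guessed at. The sector winner provably maximizes the rank-2
  approximated centered value in its environments, and the tests verify
  this against exhaustive projection over all genotypes.
* `mean_vs_stability()`: signed projection onto the average-environment
  axis (AEA, the direction of the mean environment vector) and the
  orthogonal deviation.
* `discrimination_representativeness()`: environment vector length and
  cosine with the AEA, with a median-split quadrant classification. The
  median rule is a deliberate, reproducible choice; published quadrant
  memberships read off figures are not an exact target.
* `rank_ideal()`: distances to the ideal genotype (maximal AEA
  projection, zero deviation) or ideal environment (maximal vector
  length on the axis).

```{r gge}
cm <- cell_means(gsr_yield_means())
mod <- gge_fit(cm)
mod
which_won_where(mod)
```

## The trial simulator

`simulate_trial()` generates balanced RCBD MET data from

$$y_{ijr} = \mu + g_i + e_j + \textstyle\sum_k \lambda^*_k \gamma^*_{ik}
  \delta^*_{jk} + b_{r(j)} + \varepsilon_{ijr},$$

with Gaussian effects throughout and interaction eigenvectors drawn
exactly centered and orthonormal (QR of column-centered Gaussian draws),
so the generative model is a *true* rank-$K^*$ AMMI structure and the
per-axis shares implied by the weights are exact limit statements, not
approximations. Optionally the first genotype is built with all-zero
interaction loadings, giving a subject with known ecovalence 0 and known
unit regression slope. Identical configurations reproduce identical data
byte-for-byte, and the session RNG state is restored afterwards.

The defaults emulate the packaged rice trial, back-calculated once from
its published mean squares via expected-mean-square identities
(units kg/ha): $\mu = 6700$, $\sigma_g = 300$
($\approx\sqrt{(GMS-EMS)/qr}$), $\sigma_{env} = 1600$,
$\sigma_{rep} = 1300$ (the large block mean square), $\sigma_{noise} =
1150$ ($\approx\sqrt{EMS}$), and a rank-2 interaction with weights
7500/6300 matching the observed leading singular values. What the
generator does *not* emulate: spatial field trend, heteroscedastic
environments, non-Gaussian errors, missing plots, or year-to-year
structure — so green simulation tests certify the estimators under the
stated model, not robustness to those departures.

Problem sizes in the test suite are chosen to keep the default run fast:
property loops use up to 6×6 matrices over 100 seeds, and the recovery
study uses 200 trials at the trial's own 20×12×3 shape.

## Validation results and a known limitation

`recovery_suite()` repeatedly simulates and re-analyzes trials and
summarizes the estimator sampling distributions. Two facts emerge at the
emulated trial scale:

* $\hat\sigma^2_g$ and $\hat\sigma^2_e$ are linear in the mean squares
  and recover their targets without bias.
* $h^2_B = 100\,(1 - EMS/GMS)$ is a *convex* function of the genotype
  mean square, whose per-trial coefficient of variation is large at this
  signal-to-noise ratio (the drawn genotype variance fluctuates like
  $\chi^2_{g-1}/(g-1)$, compounded by a genotype×noise cross term). Its
  Monte Carlo mean therefore sits a few percentage points *below* the
  plug-in value $h^2(\mathrm{E}[GMS], \mathrm{E}[EMS])$ — about 3
  points at the default configuration. This is a property of the ratio
  estimator itself, not an implementation defect; the corresponding
  strict recovery check in the test suite documents it by failing, and
  users comparing single-trial heritabilities near 70% should expect
  this order of downward bias.

## Other design choices

* Balanced designs only; imbalance and missing cells are rejected, never
  imputed — every formula above assumes balance.
* When only a means matrix is supplied (as with a published table), the
  replicate-level stages (`combined_anova()`, `variance_components()`,
  `ammi_anova()`) refuse to run instead of approximating an error
  stratum.
* p-values are plain F-tail probabilities; no multiple-testing
  correction is applied anywhere.
* Report files are written with 6 significant digits by default so that
  repeated runs diff cleanly; `met_run()` records MD5 checksums of every
  file it writes.
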