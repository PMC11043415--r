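# metstab

Stability analysis for multi-environment trials (MET) in plant breeding.

Breeders test candidate genotypes at many locations in replicated designs
and must decide which lines combine high mean performance with *stable*
performance across environments. `metstab` implements the complete
workflow for a balanced RCBD trial replicated across environments:

* **Combined ANOVA** with replicates nested in environments, and the
  variance-component / broad-sense heritability estimators
  σ²g = (GMS − EMS)/r, σ²e = EMS/r, h²B = 100·σ²g/σ²p;
* **AMMI** — additive main effects plus an SVD of the doubly-centered
  interaction matrix X̄ᵢⱼ − X̄ᵢ. − X̄.ⱼ + X̄.., with interaction principal
  component (IPCA) scores, per-axis variance shares, and Gollob F-tests
  (df g + q − 1 − 2k against the pooled error);
* **Six univariate stability statistics** — AMMI stability value
  ASVᵢ = √[((SS₁/SS₂)·sᵢ₁)² + sᵢ₂²], AMMI stability index
  ASIᵢ = √[(sᵢ₁θ₁²)² + (sᵢ₂θ₂²)²], Eberhart–Russell slope bᵢ, Wricke's
  ecovalence Wᵢ², Shukla's stability variance σ²ᵢ, and the weighted
  average of absolute IPCA scores (WAAS), plus the WAASY blend of
  rescaled yield and stability;
* **GGE biplot geometry as data** — environment-centered SVD with
  selectable singular-value partitioning, which-won-where hull/sector
  winners, mean-vs-stability projections onto the average-environment
  axis, discriminativeness vs representativeness, and ideal-point
  rankings;
* **A trial simulator** with a true low-rank AMMI interaction and known
  ground truth, for validating every estimator;
* **`met_run()`** plus a CLI script (`inst/cli/met-stability.R`) that
  write a full report directory with checksummed CSV/JSON outputs.

The packaged example, `gsr_yield_means()`, is the pooled paddy-yield
means of 20 Green Super Rice genotypes (18 lines + 2 checks) evaluated
at 12 locations across Pakistan in a triplicate RCBD.

## Worked example

```r
library(metstab)

cm  <- cell_means(gsr_yield_means())
fit <- ammi_fit(cm)
fit
#> AMMI fit: 20 genotypes x 12 environments, 11 interaction axes
#>   percent of interaction SS per axis:
#>     PC1: 39.2  PC2: 27.9  PC3: 13.0  PC4: 7.4  PC5: 4.1  PC6: 3.3  PC7: 2.4  PC8: 1.1  PC9: 0.9  PC10: 0.5  PC11: 0.2
#>   cumulative PC1+PC2: 67.2%
```

The first two interaction axes carry 67.2% of the G×E sum of squares:
two axes describe most of how these genotypes re-rank across locations.

```r
tab <- stability_table(cm, fit)
head(tab[order(tab$WAASY, decreasing = TRUE),
         c("genotype", "mean", "ASV", "bi", "Wi2", "WAAS", "WAASY")], 5)
#>    genotype mean   ASV     bi     Wi2   WAAS WAASY
#> 1        G1 7097 18.63 1.1076 3702862  9.981 78.32
#> 12      G12 6709  8.10 0.9087 2709037  5.951 78.01
#> 9        G9 7323 29.90 1.1829 6932132 14.495 71.15
#> 11      G11 6683 11.69 0.8965 3693599  8.669 67.90
#> 4        G4 6634 15.76 0.9751 2523087  8.205 67.69
```

G1 tops the 50/50 yield-stability blend: above-average yield (7097 kg/ha
vs a 6637 kg/ha grand mean), near-unit response slope (bᵢ = 1.11), and a
small share of the interaction SS (Wᵢ² ≈ 3.7M of the 142.8M total). G12
is the most stable line outright (lowest ASV and WAAS) at average yield.

```r
mod <- gge_fit(cm)
mod
#> GGE model (symmetric SVP): 20 genotypes x 12 environments
#>   PC1: 41.79%  PC2: 26.71%  (PC1+PC2: 68.50%)
which_won_where(mod)
#> Which-won-where geometry
#>   hull vertices (ccw): G2, G13, G20, G15, G17, G19, G6, G9
#>   sector winners:
#>     G13    <- E6
#>     G17    <- E7
#>     G2     <- E5
#>     G6     <- E8,E10
#>     G9     <- E1,E2,E3,E4,E9,E11,E12
head(rank_ideal(mod, "environments"), 3)
#>   label distance rank
#> 2    E2    25.17    1
#> 1    E1    55.32    2
#> 4    E4    58.48    3
```

The which-won-where view splits the 12 locations into five sectors; G9
wins the large mega-environment of seven locations, while G13 wins the
hot-climate site E6. E2 is the environment closest to the ideal point —
the most informative single site for ranking these genotypes.

For replicate-level data (long CSV with columns `env,gen,rep,value`),
`read_trial()` + `combined_anova()` + `variance_components()` add the
ANOVA and heritability stages, and

```sh
Rscript inst/cli/met-stability.R all --input trial.csv --out report/
```

writes the full report directory in one call.

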