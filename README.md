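# rootsoc

Analysis pipeline linking **fine-root carbon (FRC)** stocks to **soil
organic carbon (SOC)** stocks across soil-profile ("megapit"-style) site
collections, for ecosystem ecologists asking whether, where, and at what
depth root carbon inputs line up with soil carbon storage.

The pipeline:

1. **Stocks & alignment** — per-layer stocks
   (`SOC = OC%/100 × ρ × T × 10`, `FRC = B × C%/100 / 1000`, kg C m⁻²);
   root increments sampled on a fixed 10/20-cm grid are apportioned onto
   taxonomic horizons proportionally to overlap, conserving mass exactly;
   site aggregates by whole profile, organic/mineral horizon, and a 30-cm
   shallow/deep split; aridity index `MAP/(MAT + 13)`.
2. **Depth distributions** — each profile is reduced to the coefficient β
   of `Y = 1 − β^d` (cumulative stock fraction at depth *d* cm; higher β =
   deeper distribution) by bounded least squares, validated against an
   exhaustive grid-search reference.
3. **Accrual vs. priming** — FRC and SOC are z-scored per depth class
   (pooled across ecosystems) and each site's residual from the 1:1 line,
   `r = z_SOC − z_FRC`, is read as inferred net SOC accrual (`r > 0`) or
   priming (`r < 0`); shallow vs. deep standardized slopes are contrasted
   and residuals regressed on climate, clay and a micronutrient proxy.
4. **Model selection** — OLS and REML mixed models (random intercept for a
   profile-depth bin; Satterthwaite p-values) over all-subsets candidate
   sets, selected by AIC — AICc when n < 40 — with the full model
   ineligible and deterministic tie-breaking.
5. **Synthetic sites** — a seed-deterministic generator emulating the
   megapit design with known ground truth (per-site betas, totals,
   coupling parameters), so every stage above is testable end to end.

## Worked example

The `analysis/` scripts run the whole workflow on a generated 43-site
continental collection (25 forest, 15 grassland-class including 2
high-FRC tundra outliers, 2 shrubland, 1 cultivated):

```sh
Rscript analysis/01_simulate.R   # writes results/synthetic/*.csv
Rscript analysis/02_stocks.R
Rscript analysis/03_beta.R
Rscript analysis/04_accrual.R
Rscript analysis/05_models.R     # writes results/models.json
```

`02_stocks.R` prints the whole-profile regressions (seed 42):

```
grassland n=15  SOC = 13.7 + 7.0 FRC   r2 = 0.45, p = 0.00657
forest    n=25  SOC = 9.8 + 4.7 FRC   r2 = 0.02, p = 0.507
```

— a significant grassland coupling, no forest coupling; the two tundra
outliers (root biomass inflated 2.5× relative to the coupling) attenuate
the grassland slope below the generating value of 15.5, and removing them
steepens it. `03_beta.R` reduces all 86 profiles to depth-distribution
coefficients (`FRC beta: median 0.944`, `SOC beta: median 0.964` —
SOC distributed deeper than roots), each within 5×10⁻⁵ of the grid-search
reference. `05_models.R` selects, for the whole-profile analysis,

```
whole    n=43  AIC: soc_total ~ clay_profile + ecosystem_class + frc_total + mat  (pseudo R2 = 0.50)
```

i.e. FRC, MAT, clay and ecosystem class carry the signal, and the
diameter-protocol rank check is null (`Z = 0.05, p = 0.97`), as designed.

Equivalent calls from R:

```r
library(rootsoc)
d  <- synth_generate(synth_config(), seed = 42)
pp <- run_pipeline(d$tables)          # stocks, aggregates, beta, accrual
sel <- select_soc_model(pp$aggregates, random = "depth_bin")
sel$selected
```

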