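# lifeineq

Length-of-life inequality within and between population groups, from
summary mortality rates alone.

In settings without reliable vital registration — the motivating case is
Ethiopia around 2000–2011 — mortality is known only as summary rates:
under-five mortality (5q0) stratified by wealth quintile, gender or
residence from household surveys, and adult mortality (45q15) available
only nationally. `lifeineq` is for demographers and health-equity
researchers who want to turn those numbers into full distributions of age
at death and ask how much of a population's lifespan inequality group
membership actually explains.

The pipeline:

1. **Adult-mortality estimation.** Group 45q15 is estimated from the
   national rate via the groups' under-five mortality ratios `U5_i`
   (relative to the best-off group) and a normalization factor
   `x = 1 / Σ U5_i p_i`, as `45q15_i = 45q15_nat × U5_i × x`, so the
   share-weighted estimates average back to the national rate.
2. **Relational life tables.** Each group's (5q0, 45q15) pair is matched
   by the Brass logit system `Y(x) = α + β·Ys(x)` (with optional
   modified-logit correction terms `γ_x c5 + θ_x c60` anchored at ages 5
   and 60), transforming a single standard survivorship curve into the
   group's abridged life table.
3. **Inequality measures.** From each table's death distribution
   `(f_t, h_t)`: the Gini health index
   `Gini_H = 1 − (v/μ) Σ f_t h_t (1−R_t)^(v−1)` (v = 2) and
   `ALI = 2 × LE × Gini_H` (the expected lifespan gap between two random
   individuals, in years) within groups; the concentration index
   `CI = (2/μ) Σ f_t h_t R_t − 1` and the extreme-group difference in LE
   between groups.

A synthetic-data module generates survey-like inputs from a known ground
truth so every stage is testable without external data.

## Worked example

The repository is organised as an analysis workflow; the numbered scripts
under `analysis/` run the package end to end and write their outputs under
`results/`:

```sh
Rscript analysis/01_simulate_scenario.R   # synthetic 5-quintile inputs + truth
Rscript analysis/02_group_life_tables.R   # relational fits per group
Rscript analysis/03_inequality_report.R   # within/between inequality report
Rscript analysis/04_published_summaries.R # indices from published LEs
```

Step 3 prints, for the default synthetic scenario (five equal-share
quintiles spanning ~9 years of true life expectancy, adult mortality
estimated from the national rate):

```
group    LE  Gini_H   ALI     CI  Abs.diff
   G1  52.3    0.26  27.5
   G2  55.5    0.24  26.3
   G3  58.4    0.21  24.9  0.039      11.4
   G4  61.2    0.19  23.5
   G5  63.7    0.17  22.0
Total  58.2    0.22  25.3      -         -
```

Read it as: life expectancy rises and within-group inequality falls along
the socioeconomic gradient, yet even the best-off group's ALI (22.0 years
— the expected lifespan gap between two random members) is roughly twice
the 11.4-year gap between the extreme groups' life expectancies: most
lifespan inequality lives *within* groups. The same script reports
recovery errors against the generator's ground truth.

Equivalent calls in R:

```r
library(lifeineq)
scn <- generate_scenario(scenario_config(noise = FALSE))
report <- run_analysis(list(groups = scn$groups,
                            national_q45_15 = scn$national$q45_15))
report$between
#> $ci       0.0393...
#> $abs_diff 11.37...
concentration_index(c(53.4, 56.2, 60.6, 59.9, 62.5))  # 0.02994 -> 0.030
```

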