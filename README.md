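# trophlink

Quantitative trophic ecology of a demersal fish from two-season
bottom-trawl surveys, combining stomach-content analysis with muscle
stable isotopes anchored to a spatially interpolated suspension-feeder
baseline. The package is aimed at fisheries and food-web ecologists who
want the full chain — diet indices, spatial baseline, trophic levels,
ontogenetic/seasonal inference — as tested, reusable functions rather
than a one-off analysis script.

## What it computes

**Diet indices with parsimonious enumeration.** Prey individuals are
counted from stomach parts by the minimal-explanation rule (whole items
count as themselves, pooled paired structures are divided by two and
rounded up, uncountable remains attest one individual only when no
countable part of the taxon is present). From these: vacuity
%V = 100·n_empty/n_total, frequency of occurrence O_i = J_i/P over
non-empty stomachs (with rescaled %O), and numerical abundance
%N = 100·N_i/ΣN_j, per 5-cm size class, season, and pooled.

**Spatial δ¹⁵N baseline.** An empirical covariogram of baseline
observations (pairs binned by great-circle distance, pair counts as
weights), a weighted-least-squares fit of a Gaussian / exponential /
spherical covariance model c(h) = σ²·exp(−(h/a)²) (+ optional nugget),
and ordinary kriging of station-specific baseline values with the
sum-to-one weight constraint.

**Trophic levels.** Post's baseline equation
TL_i = TL_B + (δ¹⁵N_i − δ¹⁵N_B)/TDF with TL_B = 2 and TDF = 3.4 ‰, each
fish corrected by its own station's baseline, plus C:N lipid screening
(flag-only) and Table-style per-cell summaries.

**Inference.** Type-III likelihood-ratio deviance tables (sum-to-zero
contrasts, aliased columns of empty cells dropped automatically) for
binomial-logit occurrence, Poisson-log abundance and Gaussian isotope /
trophic-level models of size class, season and their interaction.

**Synthetic studies.** `simulateStudy()` draws a complete seeded survey
(spatially autocorrelated baseline field by exact Cholesky simulation,
size/season-dependent multinomial diet, empty-stomach process,
baseline-anchored isotope values) so every stage is testable against
known truth. See the methods vignette (`vignettes/trophic-pipeline.Rmd`)
for the model and every default.

## Worked example

```r
library(trophlink)
study <- simulateStudy(syntheticConfig(seed = 1))
study
#> Synthetic trophic study (seed 1 )
#>   40 trawl stations, 76 baseline observations
#>   248 fish (212 with isotopes), 713 prey-item records

vacuity(study$fish, study$prey_items, by = "season")
#>   season n_empty n_total    pct_V
#> 1 autumn      17     124 13.70968
#> 2 winter      13     124 10.48387

occurrenceIndices(study$fish, study$prey_items)
#>                     group J_i   P   O_i pct_O
#> 1                    fish 108 218 0.495 26.02
#> 2      benthic_crustacean  80 218 0.367 19.28
#> 3      pelagic_crustacean  84 218 0.385 20.24
#> 4 unidentified_crustacean  31 218 0.142  7.47
#> 5                 mollusk  59 218 0.271 14.22
#> 6                   other  53 218 0.243 12.77
```

Of 248 stomachs, 30 were empty (13.7% autumn, 10.5% winter vacuity —
the generator's empty-stomach rates are 16% and 7%, so these are within
sampling error at n = 124 per season). Fish is the most frequent prey
group: it occurs in 49.5% of the 218 non-empty stomachs.

```r
bl <- baselineForStations(study$baseline, study$stations)
bl$model
#> gaussian covariance model: sill 0.452, range 52.68 km, nugget 0 (adj R2 = 0.683)

tl <- trophicLevelTable(study$isotopes, study$fish, bl$baseline)
subset(summarizeIsotopes(tl), season == "autumn",
       c(size_class, n, d15N_mean, TL_mean, TL_sd))
#>   size_class  n d15N_mean TL_mean TL_sd
#> 1    10-15cm 16      13.4    3.84 0.175
#> 2    15-20cm 18      14.0    4.00 0.161
#> 3    20-25cm 18      15.9    4.37 0.182
#> 4    25-30cm 18      15.6    4.32 0.171
#> 5    30-35cm 22      15.3    4.35 0.146
#> 6        35+ 15      14.1    4.02 0.204
```

The covariance fit at 76 baseline points is noisy (one realisation of
the field, true sill 0.81 ‰², range 40 km), yet the kriged baselines are
good enough that per-cell mean trophic levels land close to the
configured truth (3.86, 4.06, 4.40, 4.40, 4.33, 4.10 for these cells) —
mean absolute error ~0.05 levels.

```r
resp <- fishResponseTable(study$fish, study$prey_items)
type3Table(resp, "occ_fish", "binomial_logit")
#> Type-III deviance table (binomial_logit), full model: deviance 306.6 on 237 df
#>               term df   deviance resid_deviance resid_df     p_value signif
#>         size_class  5 18.0316527       324.6523      242 0.002906995      *
#>             season  1  0.2186958       306.8393      238 0.640035443
#>  size_class:season  4  9.1416189       315.7622      241 0.057655531
```

The configured ontogenetic rise in fish prey shows as a strong
size-class effect (LR deviance 18.0 on 5 df, p = 0.003) with no season
effect, exactly the structure the generator encodes. The empty winter
10–15 cm cell is handled automatically: the interaction keeps 4 df.

`runPipeline(pipelineConfig(syntheticConfig(seed = 1)), out_dir = "out")`
chains all stages and writes the study tables, `diet_indices.csv`,
`vacuity.csv`, `baseline_kriged.csv`, `covariance_fit.json`,
`trophic_levels.csv`, `table1_summary.csv`, `table2_deviance.csv` and a
deterministic `manifest.json`. A thin CLI wrapper lives at
`inst/scripts/trophlink.R` (`simulate` and `run` subcommands).

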