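# scansoc

Social integration of group-living animals, measured from scan-sampling
records.

`scansoc` is for behavioural ecologists who collect instantaneous scan
samples of captive or wild primate groups — who is within an arm's reach
of whom (passive close proximity), and who grooms whom — and want to
know whether classes of individuals (here: rearing/deprivation
backgrounds such as non-deprived `ND`, early maternally deprived `EMD`,
and early/late long-term deprived ex-laboratory animals `ELD`/`LLD`)
differ systematically in their social integration.

The package covers the whole path from raw records to inference:

1. **Data model & IO** — tidy CSV rosters and scan tables, validated
   against closed category sets (`read_roster()`, `read_scan_table()`,
   `validate_records()`).
2. **Networks** — weighted undirected proximity and directed
   grooming-given networks, with edge weights in percent-of-scans units
   (`build_proximity_network()`, `build_grooming_network()`,
   GraphML/edge-list export).
3. **Measures** — per individual, the *vertex strength centrality*
   `s_i/(N-1)` (mean percent of scans per potential partner, 0–100) and
   the *deviation from edge weight disparity*
   `ΔY₂ = Σⱼ(w_ij/s_i)² − 1/(N-1)` (0 = spreads evenly, large = few
   preferred partners). Individuals that never groom have undefined
   disparity and are flagged, not dropped silently
   (`vertex_strength_centrality()`, `deviation_from_disparity()`,
   `metrics_table()`).
4. **Inference** — normal identity-link mixed models (group random
   intercept) per measure, ML-fitted and reduced by backward stepwise
   AICc selection under marginality, marginal F tests with residual df,
   and Holm–Bonferroni-corrected two-sided Mann–Whitney post-hocs in
   the families the retained terms license (`fit_lmm()`,
   `backward_select()`, `mann_whitney_u()`, `holm_adjust()`,
   `posthoc_pairwise()`).
5. **Synthetic data** — a calibrated generator (dyadic proximity
   probability `σᵢσⱼ`; per-scan grooming probability `γᵢ` with a
   Dirichlet-distributed, once-per-individual partner preference) so the
   full pipeline is testable by parameter recovery
   (`make_roster()`, `simulate_scans()`, `expected_measures()`).
6. **Pipeline** — one call from config to report bundle
   (`run_config()`, `run_analysis()`), plus a thin CLI
   (`inst/cli/scansoc`) with `simulate` / `measure` / `analyse` /
   `validate` subcommands.

## Worked example

Simulate the default study-like design — 41 adults in four groups (two
newly formed ex-laboratory-like groups, two stable zoo-like groups), 500
scans per group — and run the full analysis:

```r
library(scansoc)

ros <- make_roster(default_group_specs(), seed = 1)
sim <- simulate_scans(ros, default_behaviour_params(), n_scans = 500, seed = 7)
net <- build_grooming_network(sim[["ZO1"]], ros)
net
#> <scan_network> directed grooming network: 12 vertices, 500 scans (group ZO1, period P1)
round(vertex_strength_centrality(net)[1:4], 2)
#> ZO1_01 ZO1_02 ZO1_03 ZO1_04
#>   0.78   1.85   1.87   2.36
round(deviation_from_disparity(net)[1:4], 3)
#> ZO1_01 ZO1_02 ZO1_03 ZO1_04
#>  0.221  0.176  0.475  0.293
```

So individual `ZO1_04` grooms each potential partner in 2.36% of scans
on average, spreading its grooming moderately unevenly (0.293 above the
even-spread disparity). The full pipeline:

```r
bundle <- run_analysis(run_config(seed = 7))
bundle$models[["grooming:resocialisation:strength_centrality"]]$best
#> <lmm_fit> strength_centrality ~ deprivation_class + (1 | random_group)
#>   ML logLik -64.735, k = 6, n = 41, AICc = 143.941
#>   term                  F     df1   df2   p
#>   deprivation_class     17.4   3     37   0.000000323
```

Backward selection keeps only deprivation class for grooming strength
centrality, and the Holm-corrected class post-hocs read:

```r
subset(bundle$posthocs, measure == "strength_centrality" &
       behaviour == "grooming" & period == "resocialisation")
#>   level_a level_b n_a n_b  U    p_raw   p_holm significant
#> 1     ELD     EMD  10   7  6 5.39e-03 0.016157        TRUE
#> 2     ELD     LLD  10   8  2 1.83e-04 0.000914        TRUE
#> 3     ELD      ND  10  16  3 5.52e-05 0.000331        TRUE
#> 4     EMD     LLD   7   8  8 2.39e-02 0.047804        TRUE
#> 5     EMD      ND   7  16  9 1.88e-03 0.007523        TRUE
#> 6     LLD      ND   8  16 44 2.32e-01 0.232327       FALSE
```

Early long-term deprived individuals groom least (every ELD contrast
significant), early maternally deprived zoo animals groom less than
non-deprived ones, and the late-deprived vs non-deprived contrast stays
inside the noise — the qualitative integration pattern the generator's
class parameters encode.

The methods vignette (`vignettes/scan-sampling-networks.Rmd`) documents
the measures, the model-selection and post-hoc machinery, the
generator's assumptions and calibration, and known limitations.

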