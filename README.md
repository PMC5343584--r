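# kelpcast

Hindcasting the range edge of an annual kelp by coupling an ecological
niche model with a dispersal-latency occupancy automaton.

For species with dormant microscopic stages — annual kelps above all —
presence in a given year is not a direct read-out of habitat suitability:
populations persist through bad years as delayed stages ("temporal
dispersal", latency L in years) and re-colonize nearby coast by spores
("spatial dispersal", distance D in km/yr). `kelpcast` implements the full
analysis chain for this situation, aimed at biogeographers and
macroecologists who want the method runnable and testable without the
proprietary-scale rasters such studies are usually built on:

1. **Seasonal extreme-event predictors** from daily SST, wave and wind
   series: longest runs of winter/spring days above 18 °C, winter maxima,
   wave-height extremes, and the Bakun coastal upwelling index
   (Ekman transport from wind stress; favourable when > 16 m³/s per 100 m
   of coast).
2. **Pseudo-absences** outside the species' ecological space
   (Mahalanobis suitability ≤ 0.2, K-means stratified, count = presences).
3. **Monotone boosted regression trees** (SST/SWH negative, CUI positive)
   over all predictor subsets with pairwise Spearman |R| < 0.8, tuned by
   10-fold CV, ranked by temporal transferability under the Minimum
   Predicted Area criterion (threshold at sensitivity ≥ 0.9), ensembled
   by mean.
4. **Occupancy reconstruction**: from binarized suitability, a cell is
   occupied iff suitable AND (occupied within the last L years OR rescued
   from an occupied cell ≤ D km along the coast at t−1); (D, L) estimated
   by exhaustive search (1–500 km × 1–5 yr = 2500 candidates) on the
   marginal True Skill Statistic over a no-dispersal baseline.
5. **Evaluation**: pooled and per-year TSS / sensitivity / specificity,
   area through time, and persistence / extinction / recolonization maps.
6. **A synthetic coastal world** with known ground truth (seasonal and
   latitudinal SST structure, warming trend, AR(1) anomalies, discrete
   heat waves, upwelling zones, a threshold niche, and the automaton at
   known D*, L*) so the whole chain is exercised end to end.

The core statistic: TSS = sensitivity + specificity − 1 ∈ [−1, 1]. The
automaton recurrence, for suitable cells i at year t:

    occupied(i, t) ⟺ suitable(i, t) ∧
                     [ ∃ τ ∈ {t−1..t−L}: occupied(i, τ)          (latency)
                       ∨ ∃ j ≠ i: occupied(j, t−1) ∧ d(i,j) ≤ D ] (rescue)

seeded with the earliest suitability map.

## Worked example

```r
library(kelpcast)
run <- run_pipeline(seed = 1)
run
#> kelpcast pipeline run
#>   coast: 150 cells, years 1987-2014
#>   records: 242 (73 presences)
#>   ensemble: 4 model(s); MPA threshold 0.468
#>   true (D, L) = (5, 2); recovered (D, L) = (45, 1)
#>   TSS 0.791 (sens 0.945, spec 0.846); baseline TSS 0.530
```

Reading this: 242 survey records were sampled from a 28-year synthetic
truth built with dispersal 5 km/yr and latency 2 yr. Four predictor
subsets fell in the most-transferable (lowest-MPA) decile and were
ensembled; binarizing their mean prediction at the MPA threshold 0.468
and running the (D, L) grid search against the records gives a best
reconstruction with TSS 0.791 — a gain of +0.26 over the no-dispersal,
no-latency baseline (TSS 0.530). The recovered (D, L) = (45, 1) differs
from the truth because here the search runs on *modelled* suitability:
niche-model error is partly absorbed into the dispersal parameters (see
the methods vignette). Against the true suitability the search recovers
D = 5 ± 2 km and L = 2 in ≥ 80 % of replicates (acceptance criterion 4).

Stage-level functions are exported individually
(`generate_coastline()`, `generate_daily_environment()`,
`build_predictor_stack()`, `mahalanobis_suitability()`,
`draw_pseudo_absences()`, `fit_brt()`, `temporal_transferability()`,
`ensemble_predict()`, `binarize()`, `reconstruct()`, `grid_search_DL()`,
`confusion_stats()`, `area_series()`, `transition_map()`, …), and
`run$area`, `run$yearly`, `run$transitions`, `run$search$surface` hold the
stage outputs.

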