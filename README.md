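# cropwatch

Can camera traps and a farm's crop guard stand in for direct researcher
observation when monitoring wildlife foraging in crop fields?

`cropwatch` is an R package for answering that question for diurnal primates
(chacma baboons, vervet monkeys) raiding a field: it simulates ground-truth
crop-foraging events and their imperfect detection by three methods —
motion-triggered field-edge cameras, a crop guard's written log, and
researchers in a hide — then runs the full comparison pipeline on simulated
or real CSV data:

1. **Event delineation.** Camera photographs are clustered into independent
   crop-foraging events with a pooled temporal-independence window: a photo
   starts a new event iff ≥ 30 min have passed since the previous photo of
   the same species on *any* retained camera. Observer records follow the
   1-minute empty-field rule (records closer than 1 min merge).
2. **Matched-day aggregation.** Daily event counts and researcher crop-loss
   totals (items carried out of the field; unrecorded counts are `NA`, not
   zero, and excluded from loss sums) are averaged over ten-day periods using
   only days on which *all three* methods were recording.
3. **Agreement regressions.** Eight OLS fits of researcher measures on guard
   and camera event rates, per species, reported as adjusted R²
   (`1 − (1−R²)(n−1)/(n−2)`), residual SE (`√(SSE/(n−2))`), the F statistic
   (`(n−2)R²/(1−R²)` on (1, n−2) df) and its p-value.
4. **Survey-design simulation.** Every subset of the camera stations (30
   subsets at sizes 1–4 of five cameras) is re-clustered from scratch to ask
   how many cameras a deployment needs and how much placement matters
   (max/min single-camera fold ratio).

The synthetic generator encodes the study system's known detection biases:
the guard responds to 85% of baboon but only 15% of vervet incursions;
cameras fire three-shot bursts with a 5-s refractory period and trigger less
reliably on the smaller species; entries along the field edge are biased
away from the guard station; the researcher works about five days a week,
dawn to dusk.

## Worked example

```r
library(cropwatch)
res <- run_pipeline(list(mode = "synthetic", seed = 11), "run_out")
cat(render_agreement_text(res$agreement), sep = "\n")
```

```
Predictor                                Response                                   Species   AdjR2     ResidSE           F        p
------------------------------------------------------------------------------------------------------------------------------------
guard recorded crop-foraging events      researcher recorded crop loss              baboon     0.94        5.86         140    <.001 *
camera recorded crop-foraging events     researcher recorded crop loss              baboon     0.94        5.87         139    <.001 *
guard recorded crop-foraging events      researcher recorded crop-foraging events   baboon     0.98       0.242         369    <.001 *
camera recorded crop-foraging events     researcher recorded crop-foraging events   baboon     0.98       0.234         395    <.001 *
guard recorded crop-foraging events      researcher recorded crop loss              vervet     0.52        3.52        10.8     .011 *
camera recorded crop-foraging events     researcher recorded crop loss              vervet     0.73        2.66        24.8     .001 *
guard recorded crop-foraging events      researcher recorded crop-foraging events   vervet     0.51        1.15        10.4     .012 *
camera recorded crop-foraging events     researcher recorded crop-foraging events   vervet     0.88       0.574        65.8    <.001 *

* p < .05 (8 simultaneous tests, uncorrected)
```

Each row asks how well one cheap method's ten-day-period event rate predicts
a researcher-recorded measure. In this seeded run both methods track baboon
foraging almost perfectly (adj. R² ≈ 0.94–0.98), while vervet fits are
weaker — the guard misses 85% of vervet incursions and cameras trigger on
them unreliably, so their period means are noisier relative to the seasonal
signal. The camera placement summary shows the same detection asymmetry
spatially:

```r
res$subset_summary$fold_ratio
#> # A tibble: 2 × 5
#>   species max_count min_count fold_ratio defined
#>   <chr>       <int>     <int>      <dbl> <lgl>
#> 1 baboon        123         6       20.5 TRUE
#> 2 vervet         72         2       36   TRUE
```

A 20–36-fold spread between the best and worst single camera: placement
dominates, and the worst cameras are the ones beside the guard station.
`plot_subset_counts()` and `plot_station_counts()` draw the corresponding
design curves. `run_out/` also contains `events.csv`, `period_measures.csv`,
`agreement.csv`, `subsets.csv`, a plain-text summary and a JSON run
manifest; real CSV inputs run through the same pipeline via
`mode = "real"` (see `?run_pipeline`), and
`inst/scripts/run-pipeline.R` wraps it for the shell.

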