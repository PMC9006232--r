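---
title: "Methods: simulating and comparing observation methods for crop-foraging wildlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing observation methods for crop-foraging wildlife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropwatch)
```

## The problem

Direct observation by researchers is the reference standard for quantifying
wildlife incursions into crop fields, but it is expensive and does not scale.
Two low-cost alternatives are commonly available on commercial farms:
motion-triggered camera traps along the field edge, and the written log of a
crop guard employed to chase animals away. `cropwatch` implements the full
comparison pipeline for a two-species system (chacma baboons and vervet
monkeys foraging on butternut squash): it turns each method's raw records
into independent *crop-foraging events*, aggregates them onto a common
temporal grid, and asks how well the cheap methods predict the researcher
baseline — plus, for cameras, how many of them a survey design actually
needs and where they should stand.

Because the three raw data streams are rarely publishable together, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis relies on. Every downstream stage is exercised and
tested against that generator; the same functions accept real CSV inputs
through `run_pipeline()`'s real mode.

## Ground-truth event model

`generate_truth()` draws one field season of true incursions:

* **Daily counts.** Per species and day, event counts are Poisson with rate
  `daily_rate` modulated by a sinusoid over ten-day blocks
  (`seasonal_amplitude`, default 0.6). The modulation is shared between
  species. This matters: the agreement regressions operate on ten-day-period
  means, so without between-period variance in the underlying rates their
  slopes would be estimable only from noise. The sinusoid is a deliberately
  simple stand-in for the seasonal drivers (crop maturation, natural-food
  scarcity) that move real foraging rates.
* **Timing.** Both species are diurnal; starts are uniform on 06:00–18:00.
  Durations are log-normal in minutes (medians 10 and 6 min for baboons and
  vervets, `sdlog = 0.6`), putting roughly 97% of events under 30 minutes —
  field events run up to, but rarely beyond, half an hour, which is also
  what motivates the 30-minute camera independence window below. A 120-min
  cap keeps pathological tail draws inside the day.
* **Separation.** A new event requires the field to have been empty for
  `min_event_gap_min` (default 1 min). The generator enforces this
  constructively by thinning: a draw starting before the previous
  same-species event has been over for the gap is dropped. Daily counts are
  therefore marginally Poisson *before* thinning and slightly lighter after;
  at the default rates the loss is a few percent.
* **Groups and items.** Party size is `1 + Poisson(mean − 1)` (means 8 and
  3; baboons forage in larger parties). Items removed is the sum of
  per-individual Poisson draws, because the field protocol counts the squash
  each individual carries out. These are free parameters, not measured
  quantities.
* **Entry position.** Entries happen along a 100-m field edge with density
  proportional to `(5 + d)^guard_avoidance`, `d` the distance from the guard
  station (default at 0 m, exponent 1.5). This encodes the observed pattern
  that primates enter away from the guard; with exponent 0 entries are
  uniform. The offset 5 keeps the density positive at the guard itself.

## Observation models

Each simulated method reads the same truth table through its own seeded
random stream, split deterministically from the master seed — re-running or
re-parameterising one method never perturbs another's draws.

* **Researcher** (`simulate_researcher()`): on duty about five days a week
  (Monday–Friday by default, a deterministic rendering of "approximately
  five"), 06:00–18:00, and detects every on-duty event by default
  (`researcher_detect_prob = 1`) — the hide overlooks the whole 1-ha field.
  Recorded events carry exact entry/exit times; a fraction
  (`items_missing_frac`, default 0.1) of item counts goes unrecorded (`NA`).
  Missing is a distinct state from zero: those events still count as events
  but are excluded from crop-loss sums.
* **Guard** (`simulate_guard()`): on duty daily, 06:00–18:00. Each event is
  logged independently with probability 0.85 (baboons) or 0.15 (vervets) —
  guards reliably respond to the large, conspicuous species and mostly miss
  the small one. The written time is the event start plus a uniform delay of
  up to `guard_delay_min` (2 min): guards chase first and write after.
* **Cameras** (`simulate_cameras()`): an event is visible only to stations
  whose view interval contains its entry position, so placement interacts
  with the entry-position bias. Each individual's edge crossing is one
  trigger opportunity — the first individual crosses exactly at the event
  start and the rest are spread uniformly over the event duration (cameras
  see animals crossing the edge, never foraging mid-field). Each opportunity
  trips each covering camera with the species' per-passage probability
  (defaults 0.7 baboon, 0.2 vervet, reflecting body-size and group-size
  detection biases). A trigger emits a three-shot burst 1 s apart, then the
  camera is refractory for 5 s. Photo timestamps are whole seconds.

## Delineating independent events

Two rules, both in `clustering_config()`:

* **Cameras** (`cluster_detections()`): a greedy chronological scan over the
  *pooled* photo stream of all retained stations, per species. A photo opens
  a new event iff the gap to the immediately preceding same-species photo is
  at least 30 min. Numerical choices: the boundary is inclusive (a gap of
  exactly 30 min starts a new event — "at least 30 minutes had passed"); the
  gap is measured photo-to-photo, not event-start-to-photo; simultaneous
  photos on two stations are ordered stably by (timestamp, station id), and
  land in the same event either way; the scan crosses midnight freely and an
  event is dated by its start. Note the pooled rule is *non-monotone* in the
  station set: adding a camera can merge two events via a bridging photo.
  That is a property of the definition, not a bug, and is pinned by a
  regression test.
* **Observers** (`guard_records_to_events()`,
  `researcher_records_to_events()`): records closer than the 1-min
  empty-field gap merge. For researcher merges, item counts add with
  missing-propagation (`NA + x = NA` — the merged total is unknown).
  Whether a real guard's log should be deduplicated at all is not knowable
  from the protocol, so `obs_gap_min = 0` disables merging and takes the log
  verbatim.

## Matched days and ten-day periods

Ten-day periods are anchored at the analysis start date (the 100-day overlap
window divides evenly into 10); a trailing partial period is dropped with a
warning. All period means are taken over *matched days* — the intersection
of the three duty calendars — so that every method shares the same
denominator; if the researcher was absent two days of a period, the mean for
every method is over the remaining eight days. Zero is data: a duty day with
no events contributes 0, only non-duty days are missing. Camera events enter
the comparison only if they start within 06:00–18:00 (the other methods
cannot observe outside it); the full 24-h camera stream remains available to
the subset simulation.

For crop loss, an event with an unrecorded item count is excluded from the
day's item sum but still counts as an event. The alternative reading —
dropping the whole day — is not implemented as the default because it
discards the known events of that day too; the per-event exclusion keeps
the event-count and crop-loss analyses consistent with each other.

## Agreement regressions

`agreement_table()` fits eight ordinary least-squares regressions: each
species' researcher-recorded crop loss and researcher-recorded event rate
against the guard and camera event rates, over the ten-day-period means
(n = number of periods with at least one matched day). Reported per fit:
slope, intercept, R², adjusted R² `1 − (1−R²)(n−1)/(n−2)`, residual standard
error `√(SSE/(n−2))`, the F statistic `(n−2)·R²/(1−R²)` on (1, n−2) degrees
of freedom and its upper-tail p — for simple regression, identical to the
slope t-test. No multiple-testing correction is applied; the output records
the eight simultaneous tests in an attribute. A perfect fit reports
`f_stat = Inf` and the smallest positive double as p rather than 0, keeping
p in (0, 1].

## Camera-subset design simulation

`subset_event_counts()` enumerates every combination of stations at the
requested sizes (30 subsets at sizes 1–4 of five cameras, plus the full
set), restricts the photo stream to each subset, re-runs the clustering from
scratch, and counts independent events. The simulation uses the full
deployment stream by default — the design question is not tied to the
regression overlap window — with a flag to restrict it.
`subset_summary()` reports per-size spread, the single-camera table, and the
max/min fold ratio across single cameras per species (flagged undefined when
the minimum is zero). Under the default generator the cameras nearest the
guard record the fewest events, a direct consequence of the entry-position
bias.

## What the generator does and does not show

Passing tests on synthetic data demonstrate that the pipeline's rules are
implemented exactly (clustering is checked against an independent quadratic
oracle) and that the statistical machinery recovers the parameters it should
(guard response fractions within binomial error; positive agreement slopes
when rates share a seasonal signal; a higher camera R² for the reliably
triggering species). They do not certify field performance: real data carry
misidentified species, clock drift between devices, camera outages,
weather-dependent trigger sensitivity, guard literacy and motivation
effects, and behavioural feedback (deterrence, habituation) that the
generator deliberately omits. The generator is also 1-D: entry position is a
point on the edge, with no in-field movement, so it cannot represent events
entering outside the camera line.

## Problem sizes and reproducibility

The shipped tests run the generator at its default season (100 days, rates
3–4 events/day) for pipeline checks, a higher-rate season (13 events/day,
~1000+ events per species) for binomial recovery checks, and 1,000 random
photo streams of up to 200 photos for the clustering oracle — sizes chosen
to give the statistical assertions comfortable power while keeping a full
test run within a couple of minutes on one core. All randomness flows from
explicit seeds; `run_pipeline()` writes a manifest (seed, config hash,
package version, per-stage row counts) and re-running with the same config
reproduces byte-identical outputs.

## A worked run

```{r example, eval = FALSE}
res <- run_pipeline(list(mode = "synthetic", seed = 11), "run_out")
res$agreement[, c("predictor", "species", "adj_r2", "f_stat", "p_value")]
res$subset_summary$fold_ratio
plot_subset_counts(res$subset_results)
```
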