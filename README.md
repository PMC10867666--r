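# stairgaze

Gaze and gait analysis for staircase walking.

When people navigate stairs they look at some steps before stepping on
them, skip others, and occasionally glance away from the staircase
altogether — and how much of each they do depends on whether they think
the staircase is the point of the task. `stairgaze` is an R package for
analysing mobile eye-tracking recordings of stair walking: it detects the
events (saccades, step fixations, foot placements), computes the standard
summary measures of stair-gaze studies, and compares them between
instruction groups. It is aimed at researchers in visuomotor control and
natural-behaviour eye tracking who work with head-mounted trackers.

## What it computes

From four input streams per walk — a head-fixed gaze trace (deg, ~200 Hz),
blink intervals, per-scene-frame area-of-interest labels (~30 Hz), and a
vertical head-displacement trace — the pipeline derives per participant
and direction (descending / ascending):

* **Saccades**, detected where the dot product of consecutive gaze
  velocity vectors `v_i . v_(i+1)` exceeds 10 x its session median
  absolute value (fast *and* directionally consistent motion), with a 3°
  amplitude floor and a 100 ms refractory rule that removes the slower of
  two close events. Directions bin into 40 half-open 9° bins measured
  clockwise from head-fixed "up".
* **Foot placements**, as the lowest head position within each stride
  cycle of the detrended vertical displacement; they anchor each
  staircase's analysis window `[first placement - 2 s, last placement]`
  and give the time on stairs.
* **The gaze sequence** over steps, coded from frame labels with a
  two-frame minimum and same-step merging: the fraction of fixated steps
  (distinct fixated steps / step count, averaged over the two staircases),
  step-offset transition histograms split into *direct* and *indirect*
  (via "elsewhere") shifts, and the indirect share.
* **Group statistics**: a 2x2 mixed-design ANOVA (Group between,
  Direction within) with partial eta squared
  `SS_effect / (SS_effect + SS_error)` on the three dependent variables,
  Pearson correlations of time on stairs vs fraction fixated, exclusion
  bookkeeping, and a diagnostic comparing the session-adaptive detection
  threshold between groups.

A synthetic-data generator (`generate_walk`, `generate_cohort`) produces
complete recordings over a 12-step and a 9-step staircase (30 cm run,
16 cm rise, ~28° steep) with full ground truth — true saccades, the true
fixation sequence, true foot placements — so the whole pipeline is
validated by recovery simulation: noise-free walks are recovered exactly,
and cohort-level estimates track the generating parameters.

## Worked example

```r
library(stairgaze)
cohort <- generate_cohort(n_per_group = 6, seed = 42)
res <- run_pipeline(cohort)
aggregate(cbind(fraction_fixated, mean_amp_deg, time_on_stairs_s)
          ~ group + direction, data = res$summaries, FUN = \(x) round(mean(x), 3))
#>               group  direction fraction_fixated mean_amp_deg time_on_stairs_s
#> 1 stairs_irrelevant  ascending            0.641        7.253           19.292
#> 2   stairs_relevant  ascending            0.792        5.551           15.302
#> 3 stairs_irrelevant descending            0.507        7.222           13.278
#> 4   stairs_relevant descending            0.766        5.540           13.267
res$anova$fraction_fixated
#> Mixed ANOVA (12 complete participants)
#>   group            F(1,10) = 36.35, p = 0.000127, eta_p2 = 0.784
#>   direction        F(1,10) = 5.27, p = 0.0445, eta_p2 = 0.345
#>   group:direction  F(1,10) = 2.45, p = 0.1488, eta_p2 = 0.197
```

The summary table shows the two simulated instruction groups: the group
told the stairs are the task fixates more steps (~0.77-0.79 vs
~0.51-0.64), makes smaller saccades (~5.5° vs ~7.2°), and slows down less
when ascending. The ANOVA detects the group difference in the fraction of
fixated steps (F(1,10) = 36.35, p < 0.001) in this small cohort.
`res$summaries` holds one row per walk; `analyze_recording()` exposes the
per-walk events (saccades, placements, sequences) when you need them.

Recordings round-trip to plain CSV/JSON directories via
`write_cohort()` / `read_cohort()` for interoperability with other tools.

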