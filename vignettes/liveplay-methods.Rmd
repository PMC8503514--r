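---
title: "Detecting live play from accelerometry: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting live play from accelerometry: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liveplay)
```

## The detection model

Live play is defined as time when a player is on the court while the game
clock runs. The detector's premise is that on-court live seconds carry
systematically higher movement intensity than bench time and stoppages, and
that both states persist for at least several seconds — so a short moving
average of the per-second intensity, compared against a fixed threshold,
separates the two states far more reliably than any single second could.
A lone quiet second within a possession (a player parked in the corner) or
a lone burst from the bench (celebrating a basket) should not flip the
classification; averaging over the sample window absorbs exactly these.

The per-player signal chain is: band-pass filter the raw triaxial
acceleration (fourth-order Butterworth, 0.1–15 Hz, zero-phase), form the
per-second average net force `AvF_NET = mass × mean(‖a‖)` in newtons,
map it to relative exercise intensity (%V̇O₂R) through a per-player linear
calibration, smooth with a centered moving average of `window_s` seconds,
and threshold at `threshold_pct` (ties count as active). Two structural
rules follow: interior inactive runs shorter than 10 s are refilled as
active, and any second with two or fewer active players forces the whole
roster inactive. Half time is excluded by configuration. Maximal active
runs become half-open live-play periods `[start_s, end_s)`.

The assumptions worth stating explicitly:

* **Calibration is given.** The slope and intercept mapping force to %V̇O₂R
  come from laboratory testing and enter as configuration; the package does
  not estimate them. Values above 100 %V̇O₂R are retained (supramaximal
  readings are meaningful); negative values are clamped to 0.
* **Intensity separates the states.** Where a team's bench behaviour or
  slow-play tactics push the two intensity distributions together, the
  detector degrades — the known failure mode is a possession spent running
  down the clock, which reads as inactivity.
* **Periods outlast the window.** Live periods shorter than the sample
  window are rarely detected; this is documented behaviour, not a rule, and
  no minimum period duration is imposed.

## Tunable parameters

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `window_s` | s | 9 | moving-average sample window; longer windows suppress in-play lulls but blur period boundaries |
| `threshold_pct` | %V̇O₂R | 31 | activity threshold; sits at "light" activity, above sedentary bench intensity |
| `min_gap_s` | s | 10 | gap-fill cutoff: inactive runs strictly shorter are refilled (a 9 s gap fills, a 10 s gap survives) |
| `min_players_active` | players | 3 | team rule: fewer simultaneously active players blanks the second for everyone |

The defaults for `window_s` and `threshold_pct` are the optimised operating
point for semi-professional and professional basketball; `grid_search()` +
`fit_quadratic_surface()` + `optimize_surface()` re-derive them for any
dataset with a criterion annotation. The response surface around its maximum
is typically blunt — `sensitivity_table()` quantifies how little the score
moves across windows 5–15 s and thresholds 25–35 %V̇O₂R — so nearby parameter
choices perform almost identically.

## Numerical choices

**Zero-phase filtering.** The band-pass is applied forward–backward so that
detected boundaries are not delayed: a causal fourth-order filter would lag
activity onsets by several seconds and bias every period start late. The
cost is a squared magnitude response, which is immaterial for a
threshold-on-envelope method. "Fourth-order band-pass" is implemented as a
design order of 4 (eight poles), the usual reading of the MATLAB-style
`butter(4, [low high])` call in this literature. Because the 0.1 Hz edge
sits at a normalised frequency of 0.002, naive forward–backward filtering
leaves large edge transients; each pass is therefore seeded with its
direct-form steady state for the first sample and the input is extended by
odd reflection before filtering. This makes constant (gravity-only) input
map to numerically exact zero and matches textbook zero-phase results away
from the edges. The low-edge poles decay slowly (modulus ≈ 0.998), so
steady-state behaviour should only be read tens of seconds away from record
boundaries — irrelevant for whole-match records.

**Moving-average alignment.** The window is centered and shrinks at the
series edges (output length equals input length). A trailing window would
shift every boundary late by about half a window; centering keeps onsets and
offsets unbiased. For even windows the center is biased one epoch toward the
past. Both the alignment and the rule order below are deliberate fixed
choices where the method description is silent.

**Rule order.** Per-player threshold → gap-fill → team rule → exclusions →
segmentation. Gap-fill is *not* reapplied after the team rule: the team rule
exists to carve out substitution traffic, and refilling would resurrect
exactly those gaps. The team rule counts post-gap-fill activity.

**Ties and conventions.** Threshold ties are active (`≥`). The match clock
is 0-based with half-open periods, so `duration = end − start` and
segmentation round-trips exactly. Duration differences are automated −
manual. Percentiles use the linear-interpolation quantile definition;
display percentages are rounded half away from zero at one decimal while
raw values are kept at full precision (accuracy + misclassification = 100
exactly, pre-rounding).

**Agreement statistics.** Spearman's ρ uses average ranks and the
t-approximation for p. The ICC is the single-rating absolute-agreement
form from the two-way ANOVA decomposition,
`(MSR − MSE) / (MSR + MSE + 2(MSC − MSE)/n)` for two raters, with the
F-based McGraw–Wong 95% interval, computed on natural-log durations
(integer seconds ≥ 1, so the log is safe). The point estimate is identical
under the mixed and random two-way models; the label records the intended
interpretation (mixed for method-vs-method, random for two human
observers). Note the absolute-agreement form can exceed the consistency
form marginally when the between-method mean square falls below the
residual mean square; with any real systematic offset it is strictly
smaller. Period durations are paired by greedy maximal overlap in
criterion order (ties to the earliest automated period, each automated
period used once); unmatched periods are counted and reported, since the
two methods need not find equally many periods.

**Surface optimisation.** The stationary point of the fitted quadratic is
accepted only when the Hessian is negative definite and the point lies in
the grid's bounding box; otherwise each boundary edge (a one-dimensional
quadratic) is maximised exactly and the best of edges and grid cells is
returned, with the branch recorded (`analytic` / `clamped` /
`grid-fallback`). Scores are proportions of correct player-seconds rather
than raw counts so matches of different lengths pool cleanly (counts are
kept alongside); multiple matches are pooled by summing correct and total
seconds before fitting one surface.

## What the simulator emulates — and what it does not

`simulate_match()` generates: alternating live/stoppage periods with
lognormal durations (live: median 39 s, quartiles ≈ 22–60 s; stoppages:
median 25 s, floored at 10 s), four quarters via a half-time exclusion and
two longer intra-half quarter-break stoppages, a roster with exactly five
players on court per live period and substitutions only at stoppages, and
per-second intensities drawn from Gaussian active (mean 55, sd 12 %V̇O₂R)
and inactive (mean 12, sd 6, floored at 0) distributions. The lognormal
parameters are solved from the published-style median and quartile summary
(`meanlog = log(median)`, `sdlog = log(q3/q1)/(2·Φ⁻¹(0.75))`); when a
stated median is not the geometric midpoint of its quartiles no lognormal
fits both exactly, and the median is honoured. Contamination makes the
detection problem non-trivial: per-second in-play lulls (3%), bench spikes
(1%), and throw-in micro-stoppages (3–9 s of team-wide low intensity inside
a live period, probability 0.35 per period) — the last mirroring the
convention that short out-of-bounds breaks count as live play. Intensity
levels were chosen once on physiological grounds: 31 %V̇O₂R is light
activity, so live play sits well above it (55) and bench/stoppage time well
below (12), with standard deviations wide enough that single seconds
misclassify routinely and only the windowed detector recovers the schedule.

`generate_raw_accel()` additionally synthesises 100 Hz triaxial traces
(gravity on one axis, an in-band sinusoid whose per-second amplitude encodes
the target net force) so the full filter → force → calibration path is
exercised; round-tripping reproduces the target intensities to within a few
percent RMS.

The simulator does **not** model biomechanically realistic accelerometry
(impacts, jumps, orientation changes), score-line tactics such as clock
run-downs, time-out choreography, or annotation error in the criterion
itself. Passing tests therefore demonstrate that the implementation is
faithful and that the method recovers schedules with the assumed intensity
structure; they do not certify performance on real matches, where the
published validation against video annotation is the relevant evidence.

## Problem sizes used by the test-suite and acceptance script

Unit and property tests run on short synthetic series (hundreds of seconds,
8-player rosters, 1800 s match clocks) chosen to exercise every rule
boundary; the end-to-end checks run 20 seeded full-scale matches (5400 s,
10 players) for detection quality and 50 reduced-scale replicates (2700 s)
for optimiser recovery, with the planted threshold defined as the midpoint
of the active and inactive means. `scripts/acceptance.R` runs two
development and two test matches at full scale. These sizes are the
package's own choice of a desk-scale experiment: large enough that the
statistics stabilise (hundreds of periods, ~10⁵ player-seconds), small
enough to iterate on.

## Known limitations

* Output resolution is bounded by the sample window: periods shorter than
  `window_s` are usually missed, and boundary placement inherits the
  window's smoothing.
* The team rule assumes at least `min_players_active` instrumented players;
  rosters below that cannot be processed (the rule would blank everything).
* With only a team-level criterion timeline and no rotation information,
  per-player confusion counts treat bench seconds during live play as
  criterion-positive; supply per-player annotations (`player_id` column) or
  ground-truth masks for the per-player reading.
* The quadratic response surface is a local description; if the true score
  surface is multimodal over a much larger grid, the single quadratic can
  mislead. Over the default 5 × 5 grid this has not been an issue.
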