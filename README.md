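# liveplay

Automated detection of live-play periods in basketball from
accelerometry-derived relative exercise intensity.

## The problem

Basketball alternates short bouts of live play (the clock is running and a
player is on the court) with frequent stoppages. Coaches and sport
scientists want match demands quantified *per unit of live play*, but the
standard criterion — manual annotation of video footage — takes hours per
match. Players already wear trunk-mounted triaxial accelerometers, so the
live/stopped state can instead be inferred from the intensity signal itself.
`liveplay` implements such a detector, the procedure that tunes its two
parameters, and the statistical battery used to establish its criterion
validity, together with a synthetic match simulator so everything is testable
without match recordings.

## The method

Per player, raw 100 Hz triaxial acceleration **a**(t) (in g) is processed as:

1. **Band-pass filter** — fourth-order Butterworth, 0.1–15 Hz, applied
   zero-phase per axis. The 0.1 Hz edge removes gravity/DC.
2. **Average net force** per 1-s epoch:
   `AvF_NET = m · mean(‖a_filt‖)` (N), with m the player's body mass and
   ‖·‖ in m·s⁻².
3. **Relative exercise intensity** as a percentage of oxygen uptake reserve
   via a per-player linear calibration:
   `%V̇O₂R = max(0, β₁·AvF_NET + β₀)`.
4. **Moving average** of the per-second intensity over a sample window of
   *W* seconds (centered, shrinking at the edges), then **thresholding**:
   second *t* is active iff the smoothed intensity ≥ *T* %V̇O₂R.
5. **Gap filling** — interior inactive runs shorter than 10 s are
   reclassified active (stoppages last longer than that; brief low-intensity
   spells such as throw-ins do not).
6. **Team rule** — at any second with ≤ 2 active players, all players are
   set inactive (substitution traffic control); half time is forced inactive.
7. **Segmentation** of each player's mask into live-play periods
   `[start_s, end_s)`.

The parameters (*W*, *T*) are chosen by running the detector over a 5 × 5
grid (*W* ∈ {5, 10, 15, 20, 25} s, *T* ∈ {20, 25, 30, 35, 40} %V̇O₂R),
scoring each cell by the proportion of player-seconds classified identically
to the manual criterion, fitting a full bivariate quadratic
`f(W, T) = b₀ + b₁W + b₂T + b₃W² + b₄T² + b₅WT`
to the 25 scores, and maximising it analytically (with boundary and grid
fallbacks). Validity of the tuned detector is then summarised by a
per-player-second confusion matrix (accuracy, misclassification, precision,
sensitivity), Spearman's ρ and ICC(A,1) (single-rating, absolute-agreement,
two-way model on log durations, with McGraw–Wong 95% CIs) over
max-overlap-matched period durations, and the median, 5th and 95th
percentiles of the automated-minus-manual duration differences.

## Worked example

Simulate a full match (5400 s elapsed, 10-player roster, five on court per
live period, lognormal live-period durations with median 39 s), run the
detector at the default 9 s / 31 %V̇O₂R operating point, and score it against
the simulator's ground truth:

```r
library(liveplay)

sim <- simulate_match(seed = 7)
det <- detect_live_play(sim$intensity, sim$config)
det
#> Live-play detection: 10 players, 5400 s match clock
#>   team periods: 54 (median duration 40.5 s); player periods: 272
#> Detector parameters: window 9 s, threshold 31 %VO2R, gap-fill < 10 s, team rule >= 3 active

evaluate_agreement(det, manual_player_masks = sim$truth_masks)
#> Criterion validity of the automated live-play detection
#>   accuracy 99.1%  misclassification 0.9%  precision 98.6%  sensitivity 98.0%
#>   periods (player level): manual 280, automated 272, matched 270
#>   Spearman rho = 0.988 (nearly perfect), p = 1e-219
#>   ICC(A,1) on log durations = 0.984 (95% CI 0.979-0.987, excellent)
#>   bias (automated - manual): median 0 s (-3 to 2 s), within two sample windows
```

Reading the output: 99.1% of the 54 000 player-seconds were classified the
same as the ground truth; 272 per-player live-play periods were detected
against 280 true ones, with matched durations agreeing at ρ = 0.99 and an
excellent absolute-agreement ICC; the median duration error is 0 s and 90%
of errors fall within −3 to +2 s, well inside two sample windows (18 s).

Parameter optimisation works the same way from a grid:

```r
g   <- grid_search(list(intensity = sim$intensity,
                        manual_masks = sim$truth_masks, config = sim$config))
opt <- optimize_surface(fit_quadratic_surface(g))
opt$threshold_pct   # continuous optimum, %VO2R
```

A thin command-line front end with `simulate`, `detect`, `optimize` and
`evaluate` subcommands is installed at `inst/cli/liveplay.R`.

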