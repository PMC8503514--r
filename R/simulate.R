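#' Solve lognormal parameters from a median and quartiles
#'
#' `meanlog` reproduces the median exactly; `sdlog` is solved from the
#' quartile ratio, `log(q3/q1) / (2 * qnorm(0.75))`. When the stated median is
#' not the geometric mid-point of the stated quartiles (as with skewed
#' published summaries) the median is honoured exactly and the quartiles
#' approximately.
#'
#' @param median_s Target median.
#' @param q1_s,q3_s Target lower and upper quartiles.
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_from_quartiles <- function(median_s, q1_s, q3_s) {
  if (!(q1_s > 0 && median_s > 0 && q3_s > q1_s))
    stop("need 0 < q1 < q3 and a positive median", call. = FALSE)
  list(meanlog = log(median_s),
       sdlog = log(q3_s / q1_s) / (2 * stats::qnorm(0.75)))
}

#' Simulation parameters for a synthetic basketball match
#'
#' Defaults emulate semi-professional basketball: live-play period durations
#' lognormal with median 39 s and quartiles near 22-60 s, stoppages lognormal
#' with median 25 s floored at 10 s, on-court live intensity Gaussian around
#' 55 %VO2R (moderate activity), off-court/stoppage intensity around 12 %VO2R
#' (sitting, standing, walking), with occasional contamination: in-play lulls
#' (a live player idling below threshold), bench spikes (an off-court player
#' briefly active), and short throw-in micro-stoppages (< 10 s) generated
#' inside live periods as team-wide low-intensity seconds rather than as
#' schedule gaps.
#'
#' @param live_median_s,live_q1_s,live_q3_s Live-period duration summary.
#' @param stoppage_median_s,stoppage_sdlog,stoppage_min_s Stoppage duration
#'   lognormal (median/sdlog) and hard minimum.
#' @param active_mean,active_sd Gaussian intensity of on-court live seconds
#'   (%VO2R).
#' @param inactive_mean,inactive_sd Gaussian intensity of all other seconds,
#'   floored at 0.
#' @param lull_rate Per-second probability that an on-court live player reads
#'   inactive-level intensity.
#' @param spike_rate Per-second probability that an off-court player reads
#'   active-level intensity.
#' @param throwin_prob Probability that a live period contains one throw-in
#'   micro-stoppage.
#' @param throwin_min_s,throwin_max_s Throw-in duration range (whole seconds,
#'   below the 10 s gap-fill cutoff).
#' @param roster_size Number of instrumented players.
#' @param match_end_s Match clock length (seconds, tip-off to final buzzer).
#' @param half_time_s Half-time duration inserted mid-match.
#' @param quarter_break_s Stoppage duration at the two intra-half quarter
#'   breaks.
#' @param sub_prob Probability of a substitution at each stoppage.
#' @param body_mass_kg,cal_slope,cal_intercept Player mass and intensity
#'   calibration used when synthesising raw accelerometer traces.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(live_median_s = 39, live_q1_s = 22, live_q3_s = 60,
                              stoppage_median_s = 25, stoppage_sdlog = 0.45,
                              stoppage_min_s = 10,
                              active_mean = 55, active_sd = 12,
                              inactive_mean = 12, inactive_sd = 6,
                              lull_rate = 0.03, spike_rate = 0.01,
                              throwin_prob = 0.35, throwin_min_s = 3,
                              throwin_max_s = 9,
                              roster_size = 10, match_end_s = 5400,
                              half_time_s = 900, quarter_break_s = 120,
                              sub_prob = 0.6,
                              body_mass_kg = 85, cal_slope = 1,
                              cal_intercept = 0) {
  p <- as.list(environment())
  stopifnot(live_median_s > 0, live_q1_s > 0, live_q3_s > live_q1_s,
            stoppage_median_s > 0, stoppage_sdlog >= 0, stoppage_min_s >= 0,
            active_sd >= 0, inactive_sd >= 0,
            lull_rate >= 0, lull_rate < 1, spike_rate >= 0, spike_rate < 1,
            throwin_prob >= 0, throwin_prob <= 1,
            roster_size >= 1, match_end_s > half_time_s, sub_prob >= 0,
            body_mass_kg > 0, cal_slope > 0)
  ln <- lognormal_from_quartiles(live_median_s, live_q1_s, live_q3_s)
  p$live_meanlog <- ln$meanlog
  p$live_sdlog <- ln$sdlog
  structure(p, class = "simulation_params")
}

# Draw one duration (whole seconds, >= floor_s) from a lognormal.
draw_lognormal_s <- function(meanlog, sdlog, floor_s = 1) {
  max(floor_s, round(stats::rlnorm(1, meanlog, sdlog)))
}

#' Generate a synthetic match schedule
#'
#' Alternating live-play and stoppage periods drawn from the configured
#' lognormals, arranged in four quarters: a half-time break splits the match
#' clock in two, and one longer quarter-break stoppage is placed inside each
#' half. Exactly five of the roster are on court for every live period (all
#' players, with a warning, when the roster is smaller), with substitutions
#' only at stoppages. Fully reproducible from the seed.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @return An object of class `match_schedule`: `live_periods` (team-level
#'   data frame), `half_time` (start/end), `rotations` (data frame
#'   `player_id`, `start_s`, `end_s`: who was on court for each live span),
#'   `roster`, `match_end_s`, `params`, `seed`.
#' @export
generate_schedule <- function(params = simulation_params(), seed = 1) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  roster <- sprintf("P%02d", seq_len(params$roster_size))
  n_court <- 5L
  if (params$roster_size < n_court) {
    warning("roster smaller than 5: all players always on court", call. = FALSE)
    n_court <- params$roster_size
  }
  half_start <- (params$match_end_s - params$half_time_s) %/% 2L
  half_end <- half_start + params$half_time_s
  q_marks <- c(half_start %/% 2L, half_end + (params$match_end_s - half_end) %/% 2L)
  q_used <- c(FALSE, FALSE)
  stop_meanlog <- log(params$stoppage_median_s)

  oncourt <- sample(roster, n_court)
  live <- list(); rot <- list()
  t <- 0L
  repeat {
    if (t >= params$match_end_s) break
    if (t >= half_start && t < half_end) t <- half_end
    if (t >= params$match_end_s) break
    L <- draw_lognormal_s(params$live_meanlog, params$live_sdlog, floor_s = 4)
    end_t <- min(t + L, params$match_end_s,
                 if (t < half_start) half_start else params$match_end_s)
    if (end_t > t) {
      live[[length(live) + 1L]] <- c(t, end_t)
      rot[[length(rot) + 1L]] <- data.frame(player_id = oncourt,
                                            start_s = t, end_s = end_t)
    }
    t <- end_t
    # stoppage (or quarter break when a quarter mark was just crossed)
    qi <- which(!q_used & t >= q_marks)
    S <- if (length(qi)) {
      q_used[qi] <- TRUE
      params$quarter_break_s
    } else {
      draw_lognormal_s(stop_meanlog, params$stoppage_sdlog,
                       floor_s = params$stoppage_min_s)
    }
    # substitutions happen at stoppages
    if (params$roster_size > n_court && stats::runif(1) < params$sub_prob) {
      k <- sample(1:min(3, n_court), 1)
      bench <- setdiff(roster, oncourt)
      off <- sample(oncourt, k)
      on <- sample(bench, min(k, length(bench)))
      oncourt <- c(setdiff(oncourt, off[seq_along(on)]), on)
    }
    t <- t + S
  }
  lp <- do.call(rbind, lapply(live, function(x)
    data.frame(start_s = x[1], end_s = x[2])))
  lp$duration_s <- lp$end_s - lp$start_s
  structure(list(live_periods = lp,
                 half_time = c(start_s = half_start, end_s = half_end),
                 rotations = do.call(rbind, rot),
                 roster = roster,
                 match_end_s = params$match_end_s,
                 params = params, seed = seed),
            class = "match_schedule")
}

#' @export
print.match_schedule <- function(x, ...) {
  cat(sprintf("Synthetic match schedule (seed %d): %d live periods over %d s\n",
              x$seed, nrow(x$live_periods), x$match_end_s))
  cat(sprintf("  live duration median %g s (IQR %g-%g); half time [%d, %d)\n",
              stats::median(x$live_periods$duration_s),
              stats::quantile(x$live_periods$duration_s, 0.25),
              stats::quantile(x$live_periods$duration_s, 0.75),
              x$half_time[1], x$half_time[2]))
  invisible(x)
}

# Ground-truth per-player activity: on court AND clock running, as a
# seconds x roster logical matrix.
schedule_truth_masks <- function(schedule) {
  n <- schedule$match_end_s
  m <- matrix(FALSE, n, length(schedule$roster),
              dimnames = list(NULL, schedule$roster))
  r <- schedule$rotations
  for (i in seq_len(nrow(r)))
    m[(r$start_s[i] + 1L):r$end_s[i], r$player_id[i]] <- TRUE
  m
}

#' Generate per-player intensity series and ground-truth masks
#'
#' Every second of every player draws from the active intensity distribution
#' when that player is on court during live play, and from the inactive
#' distribution otherwise, with the configured contamination (lulls, bench
#' spikes, throw-in micro-stoppages). Ground truth is returned unperturbed so
#' detector output can be scored against the schedule.
#'
#' @param schedule A [generate_schedule()] result.
#' @param seed Integer seed (the schedule's own seed plus one by default, so
#'   schedule and intensity streams are independent).
#' @return List with `intensity` (named list of [intensity_series()]),
#'   `truth_masks` (seconds x roster logical matrix) and `schedule`.
#' @export
generate_intensity <- function(schedule, seed = schedule$seed + 1L) {
  stopifnot(inherits(schedule, "match_schedule"))
  params <- schedule$params
  set.seed(seed)
  n <- schedule$match_end_s
  truth <- schedule_truth_masks(schedule)

  vals <- matrix(0, n, length(schedule$roster),
                 dimnames = list(NULL, schedule$roster))
  for (j in seq_len(ncol(truth))) {
    v <- stats::rnorm(n, params$inactive_mean, params$inactive_sd)
    on <- truth[, j]
    v[on] <- stats::rnorm(sum(on), params$active_mean, params$active_sd)
    lull <- on & stats::runif(n) < params$lull_rate
    v[lull] <- stats::rnorm(sum(lull), params$inactive_mean, params$inactive_sd)
    spike <- !on & stats::runif(n) < params$spike_rate
    v[spike] <- stats::rnorm(sum(spike), params$active_mean, params$active_sd)
    vals[, j] <- v
  }
  # throw-in micro-stoppages: short team-wide low-intensity spells inside a
  # live period; the criterion still counts them as live play
  lp <- schedule$live_periods
  for (i in seq_len(nrow(lp))) {
    if (stats::runif(1) >= params$throwin_prob) next
    d <- sample(params$throwin_min_s:params$throwin_max_s, 1)
    if (lp$duration_s[i] < d + 4) next
    s0 <- lp$start_s[i] + sample.int(lp$duration_s[i] - d - 2, 1) + 1L
    idx <- (s0 + 1L):(s0 + d)
    for (j in which(truth[s0 + 1L, ]))
      vals[idx, j] <- stats::rnorm(d, params$inactive_mean, params$inactive_sd)
  }
  vals[vals < 0] <- 0
  intensity <- lapply(colnames(vals), function(id)
    intensity_series(vals[, id], player_id = id))
  names(intensity) <- colnames(vals)
  list(intensity = intensity, truth_masks = truth, schedule = schedule)
}

#' Synthesise raw 100 Hz triaxial traces from a schedule
#'
#' Builds per-player raw accelerometer traces whose per-second envelope, after
#' the signal path (band-pass filter, average net force, linear calibration
#' with the parameters in `params`), reproduces the intensity levels of
#' [generate_intensity()] to within a few percent. Each trace carries 1 g of
#' gravity on the z axis (removed by the filter's high-pass edge) and an
#' in-band sinusoidal movement component on the x axis whose amplitude tracks
#' the target per-second net force.
#'
#' @param schedule A [generate_schedule()] result.
#' @param seed Integer seed, passed to [generate_intensity()].
#' @param sample_rate_hz Sampling rate of the synthetic device (default 100).
#' @return List with `traces` (named list of raw [accel_trace()]),
#'   `intensity` (the targets), `truth_masks`, `schedule`, and `players` (a
#'   calibration table usable in [match_config()]).
#' @export
generate_raw_accel <- function(schedule, seed = schedule$seed + 1L,
                               sample_rate_hz = 100) {
  stopifnot(inherits(schedule, "match_schedule"))
  params <- schedule$params
  gen <- generate_intensity(schedule, seed = seed)
  fs <- sample_rate_hz
  traces <- lapply(names(gen$intensity), function(id) {
    v <- gen$intensity[[id]]$values
    # target per-second mean |a| (in g) that calibrates back to v %VO2R
    force <- pmax(0, (v - params$cal_intercept) / params$cal_slope)
    mean_a <- force / (params$body_mass_kg * GRAVITY_MS2)
    amp <- mean_a * pi / 2                 # mean |A sin| = 2A/pi
    amp_samples <- rep(amp, each = fs)
    f_move <- stats::runif(1, 1.5, 3)      # in-band movement frequency
    phase <- stats::runif(1, 0, 2 * pi)
    tt <- (seq_along(amp_samples) - 1) / fs
    x <- amp_samples * sin(2 * pi * f_move * tt + phase)
    accel_trace(cbind(x, 0, 1), sample_rate_hz = fs, player_id = id,
                filtered = FALSE)
  })
  names(traces) <- names(gen$intensity)
  players <- data.frame(player_id = schedule$roster,
                        mass_kg = params$body_mass_kg,
                        slope = params$cal_slope,
                        intercept = params$cal_intercept)
  c(gen, list(traces = traces, players = players))
}

#' Simulate a complete match ready for detection and evaluation
#'
#' Convenience wrapper: schedule, intensity, ground truth, the team-level
#' criterion annotation and a ready-made [match_config()] (half time as the
#' exclusion interval, detector defaults 9 s / 31 %VO2R).
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed.
#' @return List with `schedule`, `intensity`, `truth_masks`, `annotations`
#'   (team live periods as an `annotation_set`) and `config`.
#' @export
simulate_match <- function(params = simulation_params(), seed = 1) {
  schedule <- generate_schedule(params, seed)
  gen <- generate_intensity(schedule)
  config <- match_config(
    players = data.frame(player_id = schedule$roster,
                         mass_kg = params$body_mass_kg,
                         slope = params$cal_slope,
                         intercept = params$cal_intercept),
    match_end_s = schedule$match_end_s,
    exclusion_intervals = data.frame(start_s = schedule$half_time[["start_s"]],
                                     end_s = schedule$half_time[["end_s"]]),
    detector = detector_params())
  list(schedule = schedule, intensity = gen$intensity,
       truth_masks = gen$truth_masks,
       annotations = as_annotation_set(schedule$live_periods),
       config = config)
}
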