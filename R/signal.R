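# Standard gravity, g -> m s^-2.
GRAVITY_MS2 <- 9.80665

# Zero-phase (forward-backward) IIR filtering with steady-state initial
# conditions and odd-reflection padding. signal::filtfilt() leaves large edge
# transients at very low normalised cut-offs (the 0.1 Hz edge at 100 Hz), so
# each pass is seeded with the direct-form-I steady state for the first
# sample, which also makes the DC response exact on constant input.
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  dc_gain <- sum(b) / sum(a)
  one_pass <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init = rep(dc_gain * v[1], length(a) - 1L),
                              init.x = rep(v[1], length(b) - 1L)))
  }
  npad <- min(n - 1L, 3000L)
  if (npad > 0) {
    pre <- 2 * x[1] - x[(npad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  if (npad > 0) y[(npad + 1L):(npad + n)] else y
}

# Band-pass Butterworth design; returns the b/a polynomials.
butter_bandpass <- function(low_hz, high_hz, order, sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop(sprintf("cut-offs must satisfy 0 < %g < %g < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq), call. = FALSE)
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

#' Band-pass filter a raw accelerometer trace
#'
#' Applies a fourth-order Butterworth band-pass (0.1-15 Hz by default) to each
#' axis independently, zero-phase (forward-backward), so that detected
#' activity boundaries are not delayed by filter lag. The 0.1 Hz high-pass
#' edge removes the gravity/DC component; no separate gravity-vector
#' subtraction is performed.
#'
#' @param trace A raw [accel_trace()].
#' @param low_hz,high_hz Band edges in Hz. Defaults 0.1 and 15.
#' @param order Butterworth design order (per band edge). Default 4.
#' @return The filtered [accel_trace()] (`filtered = TRUE`), same length.
#' @export
bandpass_filter <- function(trace, low_hz = 0.1, high_hz = 15, order = 4) {
  stopifnot(inherits(trace, "accel_trace"))
  if (trace$filtered) stop("trace is already filtered", call. = FALSE)
  bf <- butter_bandpass(low_hz, high_hz, order, trace$sample_rate_hz)
  n <- nrow(trace$xyz)
  min_n <- 2L * 3L * (length(bf$a) - 1L)  # twice the minimum padding length
  if (n < min_n)
    stop(sprintf("trace too short to filter: %d samples, need at least %d",
                 n, min_n), call. = FALSE)
  trace$xyz <- apply(trace$xyz, 2, function(col) filtfilt_ss(bf$b, bf$a, col))
  colnames(trace$xyz) <- c("x", "y", "z")
  trace$filtered <- TRUE
  trace
}

# Analytic amplitude gain of the zero-phase band-pass at a probe frequency
# (|H|^2: the magnitude response is squared by the forward-backward pass).
bandpass_gain <- function(freq_hz, low_hz = 0.1, high_hz = 15, order = 4,
                          sample_rate_hz = 100) {
  bf <- butter_bandpass(low_hz, high_hz, order, sample_rate_hz)
  z <- exp(1i * 2 * pi * freq_hz / sample_rate_hz)
  h <- sum(bf$b * z^-(seq_along(bf$b) - 1)) / sum(bf$a * z^-(seq_along(bf$a) - 1))
  Mod(h)^2
}

#' Per-epoch average net force (AvF_NET)
#'
#' Converts a band-pass-filtered trace into average net force per 1-s epoch:
#' the Euclidean norm of the filtered acceleration vector, converted from g to
#' m s^-2, averaged over the epoch's samples and multiplied by body mass. The
#' last partial epoch is dropped.
#'
#' @param trace A filtered [accel_trace()].
#' @param mass_kg Body mass in kilograms.
#' @param epoch_s Epoch length in seconds (default 1).
#' @return Numeric vector of per-epoch forces in newtons.
#' @export
compute_avfnet <- function(trace, mass_kg, epoch_s = 1) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!trace$filtered)
    stop("trace must be band-pass filtered first (gravity would inflate force)",
         call. = FALSE)
  if (!is.finite(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be positive", call. = FALSE)
  mag <- sqrt(rowSums(trace$xyz^2)) * GRAVITY_MS2
  per_epoch <- as.integer(round(trace$sample_rate_hz * epoch_s))
  n_epochs <- length(mag) %/% per_epoch
  if (n_epochs == 0) stop("trace shorter than one epoch", call. = FALSE)
  mag <- mag[seq_len(n_epochs * per_epoch)]
  mass_kg * colMeans(matrix(mag, nrow = per_epoch))
}

#' Construct a per-second relative intensity series
#'
#' @param values Per-1-s-epoch relative exercise intensity in %VO2R, epoch 0
#'   being match-clock second 0 once aligned. Nonnegative.
#' @param avfnet Optional parallel per-epoch average net force in newtons.
#' @param player_id Optional player label.
#' @return An object of class `intensity_series`.
#' @export
intensity_series <- function(values, avfnet = NULL, player_id = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("intensity series is empty", call. = FALSE)
  if (any(!is.finite(values))) stop("intensity values must be finite", call. = FALSE)
  if (any(values < 0)) stop("intensity values must be >= 0", call. = FALSE)
  if (!is.null(avfnet) && length(avfnet) != length(values))
    stop("avfnet must parallel values", call. = FALSE)
  structure(list(values = values, avfnet = avfnet, player_id = player_id),
            class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("Relative intensity series%s: %d s, mean %.1f %%VO2R\n",
              if (is.null(x$player_id)) "" else paste0(" [", x$player_id, "]"),
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Map average net force to relative exercise intensity
#'
#' Applies a per-player linear calibration `%VO2R = slope * AvF_NET +
#' intercept`, clamped below at 0. Values above 100 are retained: they are
#' physiologically meaningful supramaximal readings.
#'
#' @param force Per-epoch AvF_NET in newtons (from [compute_avfnet()]).
#' @param slope Calibration slope in %VO2R per newton; must be positive.
#' @param intercept Calibration intercept in %VO2R.
#' @param player_id Optional player label carried through.
#' @return An [intensity_series()] with `avfnet` retained.
#' @export
calibrate_to_vo2r <- function(force, slope, intercept, player_id = NULL) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("calibration coefficients must be finite", call. = FALSE)
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  intensity_series(pmax(0, slope * force + intercept),
                   avfnet = force, player_id = player_id)
}

#' Full signal path: raw trace to relative intensity
#'
#' Convenience wrapper running [bandpass_filter()], [align_to_match_clock()],
#' [compute_avfnet()] and [calibrate_to_vo2r()] for one player, truncated to
#' the match clock.
#'
#' @param trace Raw [accel_trace()].
#' @param player_spec One row of a [match_config()] `players` table.
#' @param config The [match_config()].
#' @return An [intensity_series()] of length `config$match_end_s`.
#' @export
trace_to_intensity <- function(trace, player_spec, config) {
  filtered <- bandpass_filter(trace)
  aligned <- align_to_match_clock(filtered, config$tipoff_offset_s)
  force <- compute_avfnet(aligned, player_spec$mass_kg)
  if (length(force) < config$match_end_s)
    stop(sprintf("trace covers %d s, match clock needs %d s",
                 length(force), config$match_end_s), call. = FALSE)
  calibrate_to_vo2r(force[seq_len(config$match_end_s)],
                    slope = player_spec$slope, intercept = player_spec$intercept,
                    player_id = player_spec$player_id)
}
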