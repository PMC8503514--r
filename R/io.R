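#' Construct an accelerometer trace
#'
#' @param xyz Numeric matrix with three columns (x, y, z) in g, one row per
#'   sample at a constant rate.
#' @param sample_rate_hz Sampling rate in Hz. Must exceed 30 Hz so that the
#'   15 Hz upper band edge sits below Nyquist.
#' @param player_id Optional player label.
#' @param filtered Whether the trace has already been band-pass filtered.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(xyz, sample_rate_hz, player_id = NULL, filtered = FALSE) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns (x, y, z)", call. = FALSE)
  if (nrow(xyz) == 0) stop("trace has zero samples", call. = FALSE)
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz))) stop("trace contains non-finite values", call. = FALSE)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 30)
    stop("sample_rate_hz must exceed 30 Hz (twice the 15 Hz band edge)",
         call. = FALSE)
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, sample_rate_hz = as.numeric(sample_rate_hz),
                 player_id = player_id, filtered = isTRUE(filtered)),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("Accelerometer trace%s: %d samples at %g Hz (%.1f s)%s\n",
              if (is.null(x$player_id)) "" else paste0(" [", x$player_id, "]"),
              nrow(x$xyz), x$sample_rate_hz, nrow(x$xyz) / x$sample_rate_hz,
              if (x$filtered) ", band-pass filtered" else ", raw"))
  invisible(x)
}

#' Read a triaxial accelerometer CSV
#'
#' Expects comma-separated columns time-or-index, x, y, z with axes in g at a
#' constant, declared sample rate. An optional vendor header block (and/or a
#' column-name row) at the top of the file is skipped automatically: the data
#' proper starts at the first line whose first comma-separated field parses as
#' a number.
#'
#' @param path CSV file path.
#' @param sample_rate_hz Declared sampling rate in Hz.
#' @param player_id Optional player label attached to the trace.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path, sample_rate_hz, player_id = NULL) {
  if (!file.exists(path)) stop("accelerometer file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L)
  if (!length(head_lines)) stop("accelerometer file is empty: ", path, call. = FALSE)
  first_field <- vapply(strsplit(head_lines, ","), function(f)
    if (length(f)) f[[1]] else "", character(1))
  numeric_start <- which(!is.na(suppressWarnings(as.numeric(first_field))))
  if (!length(numeric_start))
    stop("no numeric data rows found in the first 50 lines of ", path, call. = FALSE)
  skip <- numeric_start[1] - 1L
  dat <- utils::read.csv(path, header = FALSE, skip = skip,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(dat) == 0) stop("accelerometer file has zero data rows: ", path, call. = FALSE)
  if (ncol(dat) < 4)
    stop(sprintf("accelerometer file needs 4 columns (time,x,y,z); line %d of %s has %d",
                 skip + 1L, path, ncol(dat)), call. = FALSE)
  num <- vapply(dat[, 2:4], function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(dat)))
  num <- matrix(num, ncol = 3)
  if (anyNA(num)) {
    bad_row <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("non-numeric accelerometer value on line %d of %s",
                 skip + bad_row, path), call. = FALSE)
  }
  accel_trace(num, sample_rate_hz = sample_rate_hz, player_id = player_id)
}

#' Write a trace back to the plain CSV dialect
#'
#' Columns time (seconds from trace start), x, y, z; no header. Round-trips
#' with [read_accel_csv()] at full double precision.
#'
#' @param trace An [accel_trace()].
#' @param path Output path.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  tt <- (seq_len(nrow(trace$xyz)) - 1) / trace$sample_rate_hz
  df <- data.frame(time = tt, trace$xyz)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Align a trace or intensity series to the match clock
#'
#' Discards everything recorded before tip-off so that sample (or epoch) 0 of
#' the result corresponds to match-clock second 0.
#'
#' @param x An [accel_trace()] or [intensity_series()].
#' @param tipoff_offset_s Whole seconds from the start of the recording to
#'   tip-off. Must be shorter than the recording.
#' @return The same class of object, shifted to the match clock.
#' @export
align_to_match_clock <- function(x, tipoff_offset_s) {
  UseMethod("align_to_match_clock")
}

#' @export
align_to_match_clock.accel_trace <- function(x, tipoff_offset_s) {
  dur <- nrow(x$xyz) / x$sample_rate_hz
  if (tipoff_offset_s < 0) stop("tipoff_offset_s must be nonnegative", call. = FALSE)
  if (tipoff_offset_s >= dur)
    stop(sprintf("tipoff offset (%g s) is not within the trace duration (%g s)",
                 tipoff_offset_s, dur), call. = FALSE)
  drop_n <- round(tipoff_offset_s * x$sample_rate_hz)
  if (drop_n > 0) x$xyz <- x$xyz[-seq_len(drop_n), , drop = FALSE]
  x
}

#' @export
align_to_match_clock.intensity_series <- function(x, tipoff_offset_s) {
  n <- length(x$values)
  if (tipoff_offset_s < 0) stop("tipoff_offset_s must be nonnegative", call. = FALSE)
  if (tipoff_offset_s >= n)
    stop(sprintf("tipoff offset (%g s) is not within the series duration (%d s)",
                 tipoff_offset_s, n), call. = FALSE)
  drop_n <- as.integer(round(tipoff_offset_s))
  if (drop_n > 0) {
    x$values <- x$values[-seq_len(drop_n)]
    if (!is.null(x$avfnet)) x$avfnet <- x$avfnet[-seq_len(drop_n)]
  }
  x
}

#' Read manual live-play annotations
#'
#' Annotation CSVs carry the criterion measure: live-play periods as
#' half-open `[start_s, end_s)` intervals on the match clock, with columns
#' `start_s,end_s` and optionally `player_id` (when per-player on-court spans
#' were annotated rather than one team timeline).
#'
#' @param path CSV path with a header row.
#' @param observer_id Optional label for the annotating observer.
#' @return A data frame of class `annotation_set` with columns `start_s`,
#'   `end_s`, `duration_s` and (if present in the file) `player_id`, sorted and
#'   validated non-overlapping within each timeline.
#' @export
read_annotations <- function(path, observer_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  as_annotation_set(df, observer_id = observer_id)
}

#' Validate a data frame of annotated periods
#'
#' @param df Data frame with `start_s`, `end_s` and optionally `player_id`.
#' @param observer_id Optional observer label stored as an attribute.
#' @return The validated, sorted `annotation_set`.
#' @export
as_annotation_set <- function(df, observer_id = NULL) {
  df <- as.data.frame(df)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop("annotations need columns start_s and end_s", call. = FALSE)
  split_by <- if ("player_id" %in% names(df)) df$player_id else rep("team", nrow(df))
  for (pid in unique(split_by))
    validate_intervals(df[split_by == pid, , drop = FALSE], what = "annotation period")
  df <- df[order(split_by, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  df$duration_s <- df$end_s - df$start_s
  structure(df, class = c("annotation_set", "data.frame"),
            observer_id = observer_id)
}

#' Write annotated or detected periods to CSV
#'
#' @param periods Data frame with `start_s`, `end_s` and optionally
#'   `player_id`; `duration_s` is (re)computed on write.
#' @param path Output CSV path.
#' @export
write_periods_csv <- function(periods, path) {
  periods <- as.data.frame(periods)
  periods$duration_s <- periods$end_s - periods$start_s
  keep <- intersect(c("player_id", "start_s", "end_s", "duration_s"), names(periods))
  utils::write.csv(periods[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write per-second intensity series to CSV
#'
#' Long format `player_id,second,vo2r_pct[,avfnet_n]`, the interchange format
#' between the signal stage, the simulator and the detector.
#'
#' @param series A single [intensity_series()] or a list of them.
#' @param path Output CSV path.
#' @export
write_intensity_csv <- function(series, path) {
  if (inherits(series, "intensity_series")) series <- list(series)
  any_force <- any(vapply(series, function(s) !is.null(s$avfnet), logical(1)))
  rows <- lapply(series, function(s) {
    df <- data.frame(player_id = if (is.null(s$player_id)) "P" else s$player_id,
                     second = seq_along(s$values) - 1L,
                     vo2r_pct = s$values)
    if (any_force)
      df$avfnet_n <- if (is.null(s$avfnet)) NA_real_ else s$avfnet
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read per-second intensity series from CSV
#'
#' @param path CSV with columns `player_id,second,vo2r_pct[,avfnet_n]`.
#' @return A named list of [intensity_series()], one per player.
#' @export
read_intensity_csv <- function(path) {
  if (!file.exists(path)) stop("intensity file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  needed <- c("player_id", "second", "vo2r_pct")
  if (!all(needed %in% names(df)))
    stop("intensity CSV needs columns player_id, second, vo2r_pct", call. = FALSE)
  out <- lapply(split(df, df$player_id), function(d) {
    d <- d[order(d$second), ]
    if (!identical(as.integer(d$second), seq_len(nrow(d)) - 1L))
      stop("intensity series for player ", d$player_id[1],
           " has gaps or does not start at second 0", call. = FALSE)
    force <- if ("avfnet_n" %in% names(d) && !anyNA(d$avfnet_n))
      d$avfnet_n else NULL
    intensity_series(d$vo2r_pct, avfnet = force,
                     player_id = as.character(d$player_id[1]))
  })
  out[order(names(out))]
}

#' Write a report (or any key-value result) as JSON
#'
#' @param report A named list, e.g. an agreement report or optimisation
#'   report. Unboxed scalars, full double precision.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  class(report) <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
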