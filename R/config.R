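#' Detector parameters
#'
#' Bundles the tunable inputs of the live-play detector: the moving-average
#' sample window, the relative exercise intensity threshold, the gap-filling
#' rule and the team substitution rule.
#'
#' @param window_s Moving-average sample window in seconds (positive integer).
#'   The default of 9 s is the optimised value for semi-professional and
#'   professional basketball.
#' @param threshold_pct Intensity threshold in %VO2R above which (inclusive) a
#'   smoothed second is classed active. Default 31.
#' @param min_gap_s Inactive runs strictly shorter than this, flanked by
#'   activity on both sides, are reclassified as active. Default 10 s.
#' @param min_players_active Minimum number of simultaneously active players
#'   for any player to be considered active; with the default of 3, any second
#'   with two or fewer active players is forced inactive for the whole roster
#'   (substitution artifact control).
#' @return An object of class `detector_params`.
#' @export
#' @examples
#' detector_params()
#' detector_params(window_s = 10, threshold_pct = 25)
detector_params <- function(window_s = 9, threshold_pct = 31,
                            min_gap_s = 10, min_players_active = 3) {
  window_s <- as.numeric(window_s)
  if (length(window_s) != 1 || !is.finite(window_s) || window_s < 1)
    stop("window_s must be a single number >= 1", call. = FALSE)
  if (window_s != round(window_s))
    stop("window_s must be a whole number of seconds", call. = FALSE)
  if (length(threshold_pct) != 1 || !is.finite(threshold_pct) ||
      threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must lie strictly between 0 and 100", call. = FALSE)
  if (length(min_gap_s) != 1 || !is.finite(min_gap_s) || min_gap_s < 0)
    stop("min_gap_s must be a single nonnegative number", call. = FALSE)
  if (length(min_players_active) != 1 || min_players_active < 1)
    stop("min_players_active must be >= 1", call. = FALSE)
  structure(list(window_s = as.integer(window_s),
                 threshold_pct = as.numeric(threshold_pct),
                 min_gap_s = as.numeric(min_gap_s),
                 min_players_active = as.integer(min_players_active)),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(
    "Detector parameters: window %d s, threshold %.4g %%VO2R, gap-fill < %g s, team rule >= %d active\n",
    x$window_s, x$threshold_pct, x$min_gap_s, x$min_players_active))
  invisible(x)
}

#' Match configuration
#'
#' Describes one match: the instrumented roster with per-player body mass and
#' intensity-calibration coefficients, the tip-off synchronisation offset, the
#' match clock length and intervals (half time) that are forced inactive.
#'
#' @param players A data frame with columns `player_id`, `mass_kg`, `slope`
#'   (%VO2R per newton of average net force) and `intercept` (%VO2R). One row
#'   per instrumented player.
#' @param match_end_s Length of the match clock in whole seconds; second 0 is
#'   tip-off and the clock is half-open, covering seconds `0 .. match_end_s-1`.
#' @param tipoff_offset_s Whole seconds from the start of the recorded trace to
#'   tip-off, used to align traces to the match clock.
#' @param exclusion_intervals Data frame with columns `start_s`, `end_s`
#'   (half-open, match-clock seconds) forced inactive, typically half time.
#'   `NULL` for none.
#' @param detector A [detector_params()] object holding the detector defaults
#'   for this match.
#' @return An object of class `match_config`.
#' @export
match_config <- function(players, match_end_s, tipoff_offset_s = 0,
                         exclusion_intervals = NULL,
                         detector = detector_params()) {
  players <- as.data.frame(players)
  needed <- c("player_id", "mass_kg", "slope", "intercept")
  missing_cols <- setdiff(needed, names(players))
  if (length(missing_cols))
    stop("players is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(players) == 0) stop("players must have at least one row", call. = FALSE)
  if (anyDuplicated(players$player_id))
    stop("duplicate player_id in players", call. = FALSE)
  if (any(!is.finite(players$mass_kg)) || any(players$mass_kg <= 0))
    stop("all player masses must be positive", call. = FALSE)
  match_end_s <- as.integer(match_end_s)
  if (length(match_end_s) != 1 || is.na(match_end_s) || match_end_s < 1)
    stop("match_end_s must be a positive whole number of seconds", call. = FALSE)
  if (length(tipoff_offset_s) != 1 || tipoff_offset_s < 0)
    stop("tipoff_offset_s must be a single nonnegative number", call. = FALSE)
  if (!is.null(exclusion_intervals)) {
    exclusion_intervals <- as.data.frame(exclusion_intervals)
    validate_intervals(exclusion_intervals, max_end = match_end_s,
                       what = "exclusion interval")
  }
  if (!inherits(detector, "detector_params"))
    detector <- do.call(detector_params, as.list(detector))
  structure(list(players = players,
                 match_end_s = match_end_s,
                 tipoff_offset_s = as.numeric(tipoff_offset_s),
                 exclusion_intervals = exclusion_intervals,
                 detector = detector),
            class = "match_config")
}

# Shared interval validation: columns start_s/end_s, half-open, sorted after
# sorting check, non-overlapping, optionally bounded.
validate_intervals <- function(df, max_end = NULL, what = "period") {
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop(what, "s need columns start_s and end_s", call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$end_s <= df$start_s)
  if (length(bad))
    stop(sprintf("%s(s) with end_s <= start_s at row(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  o <- order(df$start_s)
  ds <- df[o, , drop = FALSE]
  if (nrow(ds) > 1) {
    ov <- which(ds$start_s[-1] < ds$end_s[-nrow(ds)])
    if (length(ov))
      stop(sprintf("overlapping %ss: [%s,%s) and [%s,%s)", what,
                   ds$start_s[ov[1]], ds$end_s[ov[1]],
                   ds$start_s[ov[1] + 1], ds$end_s[ov[1] + 1]), call. = FALSE)
  }
  if (!is.null(max_end) && (any(df$start_s < 0) || any(df$end_s > max_end)))
    stop(sprintf("%s outside match clock [0, %s)", what, max_end), call. = FALSE)
  invisible(df)
}

#' Read a match configuration from YAML or JSON
#'
#' The document must carry `players` (list of records with `player_id`,
#' `mass_kg`, `slope`, `intercept`), `match_end_s`, and optionally
#' `tipoff_offset_s`, `exclusion_intervals` (records with `start_s`, `end_s`)
#' and `detector` (fields of [detector_params()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [match_config()] object.
#' @export
read_match_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  players <- raw$players
  if (is.list(players) && !is.data.frame(players))
    players <- do.call(rbind, lapply(players, as.data.frame))
  excl <- raw$exclusion_intervals
  if (is.list(excl) && !is.data.frame(excl) && length(excl))
    excl <- do.call(rbind, lapply(excl, as.data.frame))
  if (!is.null(excl) && !nrow(as.data.frame(excl))) excl <- NULL
  det <- if (is.null(raw$detector)) detector_params() else
    do.call(detector_params, raw$detector)
  match_config(players = players,
               match_end_s = raw$match_end_s,
               tipoff_offset_s = if (is.null(raw$tipoff_offset_s)) 0 else raw$tipoff_offset_s,
               exclusion_intervals = excl,
               detector = det)
}
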