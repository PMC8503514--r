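#' Centered moving average with shrinking edges
#'
#' Smooths a 1-s epoch series with a centered window of `window_s` epochs. At
#' the series edges the window shrinks to the available epochs, so the output
#' has the same length as the input. For even windows the center is biased one
#' epoch earlier (the window covers `floor(w/2)` past and `w/2 - 1` future
#' epochs).
#'
#' @param x Numeric per-second series (or an [intensity_series()]).
#' @param window_s Window length in whole seconds, >= 1.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' moving_average(c(0, 0, 10, 0, 0), 5)
moving_average <- function(x, window_s) {
  if (inherits(x, "intensity_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) stop("cannot smooth an empty series", call. = FALSE)
  window_s <- as.integer(window_s)
  if (is.na(window_s) || window_s < 1) stop("window_s must be >= 1", call. = FALSE)
  left <- window_s %/% 2L
  right <- window_s - 1L - left
  idx <- seq_len(n)
  lo <- pmax(1L, idx - left)
  hi <- pmin(n, idx + right)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Threshold a smoothed intensity series into an activity mask
#'
#' A second is active iff the smoothed intensity is greater than or equal to
#' the threshold (ties count as active).
#'
#' @param smoothed Numeric per-second smoothed intensity.
#' @param threshold_pct Intensity threshold in %VO2R.
#' @return Logical per-second activity mask.
#' @export
threshold_mask <- function(smoothed, threshold_pct) {
  if (inherits(smoothed, "intensity_series")) smoothed <- smoothed$values
  as.numeric(smoothed) >= threshold_pct
}

#' Reclassify short inactive gaps as active
#'
#' Every maximal inactive run strictly shorter than `min_gap_s` that is
#' flanked by active seconds on both sides becomes active; leading and
#' trailing inactive runs (pre-match, post-match) are untouched. This absorbs
#' short spells of low-intensity on-court activity that would otherwise break
#' up a live-play period, on the grounds that genuine stoppages last longer.
#'
#' @param mask Logical per-second activity mask.
#' @param min_gap_s Gap-filling cutoff in seconds (default 10: gaps of 9 s or
#'   less are filled, a 10 s gap is preserved).
#' @return Logical mask with short interior gaps filled.
#' @export
fill_short_inactive <- function(mask, min_gap_s = 10) {
  mask <- as.logical(mask)
  if (!length(mask)) return(mask)
  r <- rle(mask)
  k <- length(r$values)
  if (k < 3) return(mask)
  interior <- seq.int(2L, k - 1L)
  fill <- interior[!r$values[interior] & r$lengths[interior] < min_gap_s]
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' Team substitution rule
#'
#' At every second where the number of active players is below
#' `min_players_active`, all players are set inactive. With the default of 3
#' this implements "two or fewer active players means nobody is in live play",
#' which suppresses activity from players running on and off the court during
#' substitutions.
#'
#' @param masks Per-player activity masks: a logical matrix (seconds in rows,
#'   players in columns) or a list of equal-length logical vectors.
#' @param min_players_active Minimum simultaneous active players (default 3).
#' @return Masks in the same shape as supplied.
#' @export
apply_team_rule <- function(masks, min_players_active = 3) {
  was_list <- is.list(masks)
  m <- as_mask_matrix(masks)
  quiet <- rowSums(m) < min_players_active
  m[quiet, ] <- FALSE
  if (was_list) mask_matrix_to_list(m, names(masks)) else m
}

#' Force excluded intervals inactive
#'
#' Seconds falling inside any half-open `[start_s, end_s)` interval (typically
#' half time) are set inactive.
#'
#' @param mask Logical per-second mask on the match clock.
#' @param intervals Data frame with `start_s`, `end_s`, or `NULL` for none.
#' @return The masked logical vector.
#' @export
apply_exclusions <- function(mask, intervals) {
  mask <- as.logical(mask)
  if (is.null(intervals) || nrow(as.data.frame(intervals)) == 0) return(mask)
  intervals <- as.data.frame(intervals)
  validate_intervals(intervals, max_end = length(mask), what = "exclusion interval")
  for (i in seq_len(nrow(intervals)))
    mask[(intervals$start_s[i] + 1L):intervals$end_s[i]] <- FALSE
  mask
}

#' Segment an activity mask into periods
#'
#' Maximal runs of active seconds become half-open periods
#' `[start_s, end_s)`; `periods_to_mask()` inverts this exactly.
#'
#' @param mask Logical per-second mask.
#' @param player_id Optional label attached as a column.
#' @return Data frame with `start_s`, `end_s`, `duration_s` (and `player_id`
#'   if given), sorted; empty when the mask has no active seconds.
#' @export
segment_periods <- function(mask, player_id = NULL) {
  mask <- as.logical(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  out <- data.frame(start_s = starts[keep], end_s = ends[keep])
  out$duration_s <- out$end_s - out$start_s
  if (!is.null(player_id))
    out <- cbind(player_id = rep(player_id, nrow(out)), out)
  out
}

#' Rebuild a per-second mask from periods
#'
#' @param periods Data frame with half-open `start_s`, `end_s`.
#' @param match_end_s Mask length (match clock seconds).
#' @return Logical vector of length `match_end_s`.
#' @export
periods_to_mask <- function(periods, match_end_s) {
  mask <- rep(FALSE, match_end_s)
  periods <- as.data.frame(periods)
  for (i in seq_len(nrow(periods))) {
    s <- max(0L, periods$start_s[i]); e <- min(match_end_s, periods$end_s[i])
    if (e > s) mask[(s + 1L):e] <- TRUE
  }
  mask
}

# Coerce list-of-masks / matrix input to a seconds x players logical matrix.
as_mask_matrix <- function(masks) {
  if (is.list(masks)) {
    lens <- lengths(masks)
    if (length(unique(lens)) != 1)
      stop("player masks have mismatched lengths: ",
           paste(lens, collapse = ", "), call. = FALSE)
    m <- do.call(cbind, lapply(masks, as.logical))
    colnames(m) <- names(masks)
    m
  } else {
    m <- as.matrix(masks)
    storage.mode(m) <- "logical"
    m
  }
}

mask_matrix_to_list <- function(m, nms = NULL) {
  out <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(out) <- if (!is.null(nms)) nms else colnames(m)
  out
}

#' Detect live-play periods for a roster of players
#'
#' The full automated pipeline. Per player: centered moving average of the
#' per-second intensity over `window_s`, thresholding at `threshold_pct`
#' (active iff smoothed value >= threshold), gap-filling of interior inactive
#' runs shorter than `min_gap_s`. Across players: the team substitution rule
#' (fewer than `min_players_active` active means everyone inactive), then the
#' configured exclusion intervals (half time). Each player's mask is segmented
#' into live-play periods; the team timeline is active wherever at least
#' `min_players_active` players are active.
#'
#' @param intensity Named list of per-player [intensity_series()] (or plain
#'   numeric per-second vectors), all aligned to one match clock and at least
#'   `match_end_s` long.
#' @param config A [match_config()]; supplies `match_end_s` and exclusions.
#' @param params A [detector_params()]; defaults to `config$detector`.
#' @return An object of class `live_play_detection`: list with
#'   `player_masks` (seconds x players logical matrix), `player_periods`,
#'   `team_mask`, `team_periods`, `active_count` (players active per second)
#'   and the `params` used.
#' @export
detect_live_play <- function(intensity, config, params = config$detector) {
  if (!inherits(params, "detector_params"))
    params <- do.call(detector_params, as.list(params))
  if (!is.list(intensity) || inherits(intensity, "intensity_series"))
    intensity <- list(intensity)
  if (length(intensity) < params$min_players_active)
    stop(sprintf("%d player(s) supplied but min_players_active = %d: the team rule would blank everything",
                 length(intensity), params$min_players_active), call. = FALSE)
  n <- config$match_end_s
  values <- lapply(intensity, function(s) {
    v <- if (inherits(s, "intensity_series")) s$values else as.numeric(s)
    if (length(v) < n)
      stop(sprintf("intensity series (%d s) shorter than match clock (%d s)",
                   length(v), n), call. = FALSE)
    v[seq_len(n)]
  })
  ids <- names(intensity)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(seq_along(intensity), function(i) {
      s <- intensity[[i]]
      if (inherits(s, "intensity_series") && !is.null(s$player_id))
        as.character(s$player_id) else paste0("P", i)
    }, character(1))
  }

  per_player <- lapply(values, function(v) {
    sm <- moving_average(v, params$window_s)
    fill_short_inactive(threshold_mask(sm, params$threshold_pct),
                        params$min_gap_s)
  })
  m <- do.call(cbind, per_player)
  colnames(m) <- ids
  m <- apply_team_rule(m, params$min_players_active)
  m <- apply(m, 2, apply_exclusions, intervals = config$exclusion_intervals)
  colnames(m) <- ids

  player_periods <- do.call(rbind, lapply(ids, function(id)
    segment_periods(m[, id], player_id = id)))
  if (is.null(player_periods))
    player_periods <- data.frame(player_id = character(), start_s = integer(),
                                 end_s = integer(), duration_s = integer())
  active_count <- rowSums(m)
  team_mask <- active_count >= params$min_players_active
  structure(list(player_masks = m,
                 player_periods = player_periods,
                 team_mask = team_mask,
                 team_periods = segment_periods(team_mask, player_id = "team"),
                 active_count = active_count,
                 params = params),
            class = "live_play_detection")
}

#' @export
print.live_play_detection <- function(x, ...) {
  cat(sprintf("Live-play detection: %d players, %d s match clock\n",
              ncol(x$player_masks), nrow(x$player_masks)))
  cat(sprintf("  team periods: %d (median duration %s s); player periods: %d\n",
              nrow(x$team_periods),
              if (nrow(x$team_periods)) format(stats::median(x$team_periods$duration_s)) else "-",
              nrow(x$player_periods)))
  print(x$params)
  invisible(x)
}
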