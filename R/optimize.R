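#' Per-second agreement score between automated and manual masks
#'
#' Counts player-seconds where the automated activity state equals the manual
#' criterion state, summed over players.
#'
#' @param auto_masks,manual_masks Per-player logical masks (matrix or list),
#'   aligned, same players, same length.
#' @return List with `correct`, `total` and `proportion` (correct/total).
#' @export
score_parameters <- function(auto_masks, manual_masks) {
  a <- as_mask_matrix(auto_masks)
  m <- as_mask_matrix(manual_masks)
  if (!all(dim(a) == dim(m)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(m), ncol(m)), call. = FALSE)
  if (!is.null(colnames(a)) && !is.null(colnames(m)) &&
      !identical(sort(colnames(a)), sort(colnames(m))))
    stop("mask rosters differ", call. = FALSE)
  if (!is.null(colnames(a)) && !is.null(colnames(m)))
    m <- m[, colnames(a), drop = FALSE]
  correct <- sum(a == m)
  total <- length(a)
  list(correct = correct, total = total, proportion = correct / total)
}

#' Grid search over sample window and intensity threshold
#'
#' Runs the full detector for every combination of window and threshold and
#' scores each against the manual criterion masks. Several matches may be
#' supplied; their correct and total player-second counts are pooled per cell
#' before the proportion is formed, so matches of different length contribute
#' by their duration.
#'
#' @param matches One match, or a list of matches, each a list with elements
#'   `intensity` (per-player series, see [detect_live_play()]), `manual_masks`
#'   (per-player logical criterion masks, seconds x players) and `config`
#'   (a [match_config()]).
#' @param windows_s Candidate sample windows in seconds. Default
#'   `c(5, 10, 15, 20, 25)`.
#' @param thresholds_pct Candidate thresholds in %VO2R. Default
#'   `c(20, 25, 30, 35, 40)`.
#' @return A data frame of class `parameter_grid` with one row per cell:
#'   `window_s`, `threshold_pct`, `correct`, `total`, `score`.
#' @export
grid_search <- function(matches, windows_s = c(5, 10, 15, 20, 25),
                        thresholds_pct = c(20, 25, 30, 35, 40)) {
  if (!is.null(matches$intensity)) matches <- list(matches)
  if (length(windows_s) < 2 || length(thresholds_pct) < 2)
    stop("grid needs at least two windows and two thresholds", call. = FALSE)
  cells <- expand.grid(window_s = windows_s, threshold_pct = thresholds_pct,
                       KEEP.OUT.ATTRS = FALSE)
  cells$correct <- 0; cells$total <- 0
  for (i in seq_len(nrow(cells))) {
    for (mt in matches) {
      params <- detector_params(
        window_s = cells$window_s[i], threshold_pct = cells$threshold_pct[i],
        min_gap_s = mt$config$detector$min_gap_s,
        min_players_active = mt$config$detector$min_players_active)
      det <- tryCatch(detect_live_play(mt$intensity, mt$config, params),
                      error = function(e) stop(sprintf(
                        "detector failed at cell (W=%g, T=%g): %s",
                        cells$window_s[i], cells$threshold_pct[i],
                        conditionMessage(e)), call. = FALSE))
      sc <- score_parameters(det$player_masks, mt$manual_masks)
      cells$correct[i] <- cells$correct[i] + sc$correct
      cells$total[i] <- cells$total[i] + sc$total
    }
  }
  cells$score <- cells$correct / cells$total
  class(cells) <- c("parameter_grid", "data.frame")
  cells
}

#' Fit a second-order response surface to grid scores
#'
#' Ordinary least squares of the agreement score on
#' `1, W, T, W^2, T^2, W*T` over the grid cells.
#'
#' @param grid A [grid_search()] result, or any data frame with `window_s`,
#'   `threshold_pct` and `score`.
#' @return An object of class `surface_model`: coefficients `b0..b5`, the
#'   Pearson correlation `fit_r` between fitted and observed scores (`NaN`
#'   with a warning when the scores are constant), and the underlying data.
#' @export
fit_quadratic_surface <- function(grid) {
  grid <- as.data.frame(grid)
  if (nrow(grid) < 6)
    stop("need at least 6 grid cells to fit 6 coefficients", call. = FALSE)
  W <- grid$window_s; T <- grid$threshold_pct; y <- grid$score
  fit <- stats::lm(y ~ W + T + I(W^2) + I(T^2) + I(W * T))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design: the grid does not span both parameters",
         call. = FALSE)
  names(beta) <- paste0("b", 0:5)
  fitted_y <- stats::fitted(fit)
  if (stats::sd(y) == 0 || stats::sd(fitted_y) == 0) {
    warning("constant scores: surface fit quality is undefined", call. = FALSE)
    fit_r <- NaN
  } else {
    fit_r <- stats::cor(fitted_y, y)
  }
  structure(list(coefficients = beta, fit_r = fit_r, grid = grid,
                 fitted = fitted_y),
            class = "surface_model")
}

#' Evaluate a fitted surface
#'
#' @param object A `surface_model`.
#' @param window_s,threshold_pct Coordinates (vectorised).
#' @param ... Unused.
#' @return Predicted score(s).
#' @export
predict.surface_model <- function(object, window_s, threshold_pct, ...) {
  b <- object$coefficients
  b[1] + b[2] * window_s + b[3] * threshold_pct + b[4] * window_s^2 +
    b[5] * threshold_pct^2 + b[6] * window_s * threshold_pct
}

#' @export
print.surface_model <- function(x, ...) {
  cat("Second-order response surface over (window, threshold)\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  fit r (fitted vs observed) = %s\n", format(x$fit_r, digits = 4)))
  invisible(x)
}

#' Analytic optimum of a fitted response surface
#'
#' Solves the stationary-point system of the quadratic and accepts it only if
#' the Hessian is negative definite (a true maximum) and the point lies inside
#' the bounds. Otherwise the surface is maximised over the boundary edges
#' (each a one-dimensional quadratic, solved exactly) and the observed grid
#' cells, and the best candidate is returned. The branch taken is recorded in
#' `source` (`"analytic"`, `"clamped"` or `"grid-fallback"`).
#'
#' @param model A [fit_quadratic_surface()] result.
#' @param bounds List with `window_s = c(min, max)` and
#'   `threshold_pct = c(min, max)`; defaults to the grid bounding box.
#' @return List with `window_s`, `threshold_pct` (full precision),
#'   `window_s_int`, `threshold_pct_int` (rounded for detector use), the
#'   predicted `value` and `source`.
#' @export
optimize_surface <- function(model, bounds = NULL) {
  stopifnot(inherits(model, "surface_model"))
  b <- model$coefficients
  if (is.null(bounds))
    bounds <- list(window_s = range(model$grid$window_s),
                   threshold_pct = range(model$grid$threshold_pct))
  wlim <- bounds$window_s; tlim <- bounds$threshold_pct

  finish <- function(w, t, source) {
    w <- unname(w); t <- unname(t)
    list(window_s = w, threshold_pct = t,
         window_s_int = as.integer(round(w)),
         threshold_pct_int = as.integer(round(t)),
         value = unname(predict(model, w, t)), source = source)
  }

  H <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2, 2)
  detH <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  st <- if (is.finite(detH) && detH != 0)
    tryCatch(solve(H, -c(b[2], b[3])), error = function(e) NULL) else NULL
  singular <- is.null(st) || !all(is.finite(st))
  if (!singular) {
    neg_def <- H[1, 1] < 0 && detH > 0
    inside <- st[1] >= wlim[1] && st[1] <= wlim[2] &&
      st[2] >= tlim[1] && st[2] <= tlim[2]
    if (neg_def && inside) return(finish(st[1], st[2], "analytic"))
  }

  # Boundary: each edge restricts f to a 1-D quadratic; evaluate endpoints
  # and (if concave) the interior vertex.
  edge_candidates <- function(fixed, which_fixed) {
    if (which_fixed == "W") {
      # f(T) = const + (b2 + b5*W) T + b4 T^2
      lin <- b[3] + b[6] * fixed; quad <- b[5]
      cand <- tlim
      if (quad < 0) {
        v <- -lin / (2 * quad)
        if (v > tlim[1] && v < tlim[2]) cand <- c(cand, v)
      }
      cbind(W = fixed, T = cand)
    } else {
      lin <- b[2] + b[6] * fixed; quad <- b[4]
      cand <- wlim
      if (quad < 0) {
        v <- -lin / (2 * quad)
        if (v > wlim[1] && v < wlim[2]) cand <- c(cand, v)
      }
      cbind(W = cand, T = fixed)
    }
  }
  cand <- rbind(edge_candidates(wlim[1], "W"), edge_candidates(wlim[2], "W"),
                edge_candidates(tlim[1], "T"), edge_candidates(tlim[2], "T"),
                cbind(W = model$grid$window_s, T = model$grid$threshold_pct))
  vals <- predict(model, cand[, "W"], cand[, "T"])
  best <- which.max(vals)
  src <- if (singular) "grid-fallback" else "clamped"
  if (singular) {
    gbest <- which.max(model$grid$score)
    return(finish(model$grid$window_s[gbest], model$grid$threshold_pct[gbest],
                  "grid-fallback"))
  }
  finish(cand[best, "W"], cand[best, "T"], src)
}

#' Near-flat-maximum sensitivity summary
#'
#' Reports how much the fitted score surface varies across a stated parameter
#' neighbourhood (by default windows 5-15 s and thresholds 25-35 %VO2R), as
#' the absolute and percentage change relative to the best value in that
#' region, together with the same summary over the observed grid cells that
#' fall inside the region.
#'
#' @param model A [fit_quadratic_surface()] result.
#' @param window_range,threshold_range Region of interest.
#' @return List with `surface_range`, `surface_pct_change`, `grid_range`,
#'   `grid_pct_change` and the region used.
#' @export
sensitivity_table <- function(model, window_range = c(5, 15),
                              threshold_range = c(25, 35)) {
  stopifnot(inherits(model, "surface_model"))
  ws <- seq(window_range[1], window_range[2], length.out = 41)
  ts <- seq(threshold_range[1], threshold_range[2], length.out = 41)
  gr <- expand.grid(W = ws, T = ts)
  v <- predict(model, gr$W, gr$T)
  g <- model$grid
  ing <- g$window_s >= window_range[1] & g$window_s <= window_range[2] &
    g$threshold_pct >= threshold_range[1] & g$threshold_pct <= threshold_range[2]
  gs <- g$score[ing]
  list(window_range = window_range, threshold_range = threshold_range,
       surface_range = max(v) - min(v),
       surface_pct_change = 100 * (max(v) - min(v)) / max(v),
       grid_range = if (length(gs)) max(gs) - min(gs) else NA_real_,
       grid_pct_change = if (length(gs)) 100 * (max(gs) - min(gs)) / max(gs)
                         else NA_real_)
}
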