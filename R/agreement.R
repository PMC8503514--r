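# Round half away from zero at `digits` decimals (display convention for
# percentages; raw values are always retained unrounded).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-second confusion counts
#'
#' Cross-tabulates every player-second by manual criterion state (rows;
#' positive class = on court in live play) against automated state (columns).
#'
#' @param auto_masks,manual_masks Per-player logical masks (matrix or list),
#'   aligned, same roster and length.
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(auto_masks, manual_masks) {
  a <- as_mask_matrix(auto_masks)
  m <- as_mask_matrix(manual_masks)
  if (!all(dim(a) == dim(m)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(m), ncol(m)), call. = FALSE)
  if (!is.null(colnames(a)) && !is.null(colnames(m)))
    m <- m[, colnames(a), drop = FALSE]
  structure(list(tp = sum(m & a), fn = sum(m & !a),
                 fp = sum(!m & a), tn = sum(!m & !a)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  tot <- x$tp + x$fn + x$fp + x$tn
  cat("Confusion counts (player-seconds; rows manual, columns automated)\n")
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d   total %d\n",
              x$tp, x$fn, x$fp, x$tn, tot))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, misclassification `(fn+fp)/total`, precision
#' `tp/(tp+fp)` and sensitivity `tp/(tp+fn)`, each as a percentage. Raw
#' (unrounded) values are returned alongside one-decimal display values
#' (rounded half away from zero). Accuracy and misclassification sum to 100
#' exactly before rounding.
#'
#' @param counts A [confusion_counts()] object, or a list/vector with `tp`,
#'   `fn`, `fp`, `tn`.
#' @return List with `accuracy`, `misclassification`, `precision`,
#'   `sensitivity` (percent, full precision) and a `display` sub-list rounded
#'   to one decimal. Precision is `NaN` when `tp+fp = 0`, sensitivity when
#'   `tp+fn = 0`.
#' @export
classification_metrics <- function(counts) {
  counts <- unclass(as.list(counts))
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  total <- tp + fn + fp + tn
  if (total <= 0) stop("confusion counts are empty", call. = FALSE)
  out <- list(
    accuracy = 100 * (tp + tn) / total,
    misclassification = 100 * (fn + fp) / total,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NaN,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN)
  out$display <- lapply(out, round_half_away, digits = 1)
  out
}

#' Pair manual and automated periods by maximal overlap
#'
#' Greedy matching in manual order: each manual period is paired with the
#' not-yet-used automated period sharing the largest temporal overlap (ties
#' broken toward the earliest automated period). Manual periods with zero
#' overlap against every remaining automated period, and automated periods
#' never chosen, are returned unmatched.
#'
#' @param manual_periods,auto_periods Data frames with half-open `start_s`,
#'   `end_s`, sorted by start.
#' @return List with `pairs` (data frame: manual and automated start/end/
#'   duration plus `overlap_s`), `unmatched_manual`, `unmatched_auto`.
#' @export
match_periods <- function(manual_periods, auto_periods) {
  man <- as.data.frame(manual_periods)
  aut <- as.data.frame(auto_periods)
  man <- man[order(man$start_s), , drop = FALSE]
  aut <- aut[order(aut$start_s), , drop = FALSE]
  used <- rep(FALSE, nrow(aut))
  rows <- vector("list", nrow(man))
  matched_man <- rep(FALSE, nrow(man))
  for (i in seq_len(nrow(man))) {
    if (!nrow(aut)) break
    ov <- pmin(man$end_s[i], aut$end_s) - pmax(man$start_s[i], aut$start_s)
    ov[used] <- -Inf
    j <- which.max(ov)  # first maximum = earliest automated period on ties
    if (length(j) && is.finite(ov[j]) && ov[j] > 0) {
      used[j] <- TRUE
      matched_man[i] <- TRUE
      rows[[i]] <- data.frame(
        manual_start_s = man$start_s[i], manual_end_s = man$end_s[i],
        manual_duration_s = man$end_s[i] - man$start_s[i],
        auto_start_s = aut$start_s[j], auto_end_s = aut$end_s[j],
        auto_duration_s = aut$end_s[j] - aut$start_s[j],
        overlap_s = ov[j])
    }
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(manual_start_s = numeric(), manual_end_s = numeric(),
                        manual_duration_s = numeric(), auto_start_s = numeric(),
                        auto_end_s = numeric(), auto_duration_s = numeric(),
                        overlap_s = numeric())
  list(pairs = pairs,
       unmatched_manual = man[!matched_man, , drop = FALSE],
       unmatched_auto = aut[!used, , drop = FALSE])
}

# Hopkins-style qualitative band for a correlation magnitude.
classify_correlation <- function(r) {
  a <- abs(r)
  if (is.na(a)) return(NA_character_)
  if (a >= 0.90) "nearly perfect"
  else if (a >= 0.70) "very large"
  else if (a >= 0.50) "large"
  else if (a >= 0.30) "moderate"
  else if (a >= 0.10) "small"
  else "trivial"
}

# Cicchetti band for an ICC.
classify_icc <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' Spearman's rank correlation
#'
#' Rank correlation with average ranks for ties, computed as the Pearson
#' correlation of the rank vectors; the p-value uses the t approximation on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors (e.g. manual and automated period
#'   durations), length >= 3.
#' @return List with `rho`, `p`, `n` and a qualitative `band` (Hopkins
#'   scale: large, very large, nearly perfect, ...). `rho` is `NA` with a
#'   warning when either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman's rho is undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, band = NA_character_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, band = classify_correlation(rho))
}

#' Single-rating absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way ANOVA decomposition with subjects (periods) as rows and the two
#' methods as raters, following McGraw & Wong: `ICC(A,1) = (MSR - MSE) /
#' (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The 95% confidence interval uses
#' the F-based method of McGraw & Wong. Absolute agreement penalises a
#' systematic offset between methods, unlike the consistency form (also
#' returned for reference). The point estimate is identical under the
#' two-way mixed and two-way random models; the `model` argument is a label
#' recording which interpretation is intended.
#'
#' @param x,y Paired measurements (x = rater/method 1, y = rater/method 2),
#'   length >= 5.
#' @param model `"mixed"` (two-way mixed effects; methods fixed) or
#'   `"random"` (two-way random; e.g. two human observers).
#' @param log_transform Take natural logs first (all values must be >= 1 s as
#'   durations are whole seconds). Default `TRUE`, the convention for
#'   right-skewed duration data.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `p` (F test of ICC = 0),
#'   `icc_consistency`, mean squares, `model`, `log_transformed`, `n`, and a
#'   Cicchetti `band` (poor/fair/good/excellent). `icc` is `NA` with a
#'   warning when there is no between-subject variance.
#' @export
icc_absolute_agreement <- function(x, y, model = c("mixed", "random"),
                                   log_transform = TRUE, conf_level = 0.95) {
  model <- match.arg(model)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 5) stop("need at least 5 pairs", call. = FALSE)
  if (log_transform) {
    if (any(x < 1) || any(y < 1))
      stop("log transform requires all values >= 1", call. = FALSE)
    x <- log(x); y <- log(y)
  }
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || sum((row_means - grand)^2) == 0) {
    warning("no between-subject variance: ICC is undefined", call. = FALSE)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, icc_consistency = NA_real_, msr = msr,
                msc = msc, mse = mse, model = model,
                log_transformed = log_transform, n = n, band = NA_character_))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf_level
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  fstat <- msr / mse
  p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, p = p,
       icc_consistency = icc_c, msr = msr, msc = msc, mse = mse,
       model = model, log_transformed = log_transform, n = n,
       band = classify_icc(icc))
}

#' Median bias and 5th/95th percentiles of duration differences
#'
#' Differences are automated minus manual. Percentiles use the
#' linear-interpolation quantile definition. When the sample window is
#' supplied, the report flags whether both percentile bounds lie within twice
#' the window duration, the stated benchmark for reasonable absolute
#' agreement.
#'
#' @param auto_durations,manual_durations Paired durations in seconds.
#' @param window_s Optional sample window for the agreement flag.
#' @return List with `median`, `p5`, `p95` (seconds), `n`, and (when
#'   `window_s` is given) `within_two_windows`.
#' @export
bias_percentiles <- function(auto_durations, manual_durations, window_s = NULL) {
  if (length(auto_durations) != length(manual_durations))
    stop("durations must be paired", call. = FALSE)
  if (!length(auto_durations)) stop("need at least 1 pair", call. = FALSE)
  d <- auto_durations - manual_durations
  q <- unname(stats::quantile(d, c(0.05, 0.5, 0.95), type = 7))
  out <- list(median = q[2], p5 = q[1], p95 = q[3], n = length(d))
  if (!is.null(window_s))
    out$within_two_windows <- max(abs(c(q[1], q[3]))) < 2 * window_s
  out
}

#' Full criterion-validity evaluation
#'
#' Compares a [detect_live_play()] result with manual criterion annotations:
#' per-player-second confusion matrix and classification metrics, plus
#' per-period relative agreement (Spearman's rho), absolute agreement
#' (ICC(A,1) on log durations with 95% CI) and median bias with 5th/95th
#' percentiles of the automated-minus-manual duration differences, computed
#' on max-overlap matched period pairs.
#'
#' Periods are compared per player when a per-player criterion is available
#' (`manual_player_masks`, or a `player_id` column in `manual_periods`),
#' pooling pairs across players; otherwise team timelines are compared.
#'
#' @param detection A [detect_live_play()] result.
#' @param manual_periods Team-level criterion periods (data frame or
#'   `annotation_set`, half-open seconds); may carry a `player_id` column.
#' @param manual_player_masks Optional per-player criterion masks (seconds x
#'   players logical matrix) when on-court rotation is known, e.g. the
#'   simulator's ground truth. Overrides mask construction from
#'   `manual_periods`.
#' @param conf_level Confidence level for the ICC interval.
#' @return An object of class `agreement_report`.
#' @export
evaluate_agreement <- function(detection, manual_periods = NULL,
                               manual_player_masks = NULL, conf_level = 0.95) {
  stopifnot(inherits(detection, "live_play_detection"))
  n_sec <- nrow(detection$player_masks)
  ids <- colnames(detection$player_masks)
  per_player_criterion <- !is.null(manual_player_masks) ||
    (!is.null(manual_periods) && "player_id" %in% names(manual_periods))

  if (is.null(manual_player_masks)) {
    if (is.null(manual_periods))
      stop("supply manual_periods and/or manual_player_masks", call. = FALSE)
    if (per_player_criterion) {
      manual_player_masks <- vapply(ids, function(id)
        periods_to_mask(manual_periods[manual_periods$player_id == id, , drop = FALSE],
                        n_sec), logical(n_sec))
    } else {
      team <- periods_to_mask(manual_periods, n_sec)
      manual_player_masks <- matrix(team, nrow = n_sec, ncol = length(ids),
                                    dimnames = list(NULL, ids))
    }
  }
  manual_player_masks <- as_mask_matrix(manual_player_masks)
  if (nrow(manual_player_masks) != n_sec)
    stop("manual masks do not cover the match clock", call. = FALSE)

  counts <- confusion_counts(detection$player_masks, manual_player_masks)
  metrics <- classification_metrics(counts)

  # Period-level comparison.
  if (per_player_criterion) {
    pair_list <- lapply(ids, function(id) {
      man <- segment_periods(manual_player_masks[, id])
      aut <- detection$player_periods[detection$player_periods$player_id == id, ,
                                      drop = FALSE]
      match_periods(man, aut)
    })
    pairs <- do.call(rbind, lapply(pair_list, `[[`, "pairs"))
    n_manual <- sum(vapply(pair_list, function(p)
      nrow(p$pairs) + nrow(p$unmatched_manual), numeric(1)))
    n_auto <- sum(vapply(pair_list, function(p)
      nrow(p$pairs) + nrow(p$unmatched_auto), numeric(1)))
    level <- "player"
  } else {
    man_team <- segment_periods(periods_to_mask(manual_periods, n_sec))
    mp <- match_periods(man_team, detection$team_periods)
    pairs <- mp$pairs
    n_manual <- nrow(man_team)
    n_auto <- nrow(detection$team_periods)
    level <- "team"
  }

  enough <- nrow(pairs) >= 5
  rho <- if (nrow(pairs) >= 3)
    spearman_rho(pairs$manual_duration_s, pairs$auto_duration_s) else NULL
  icc <- if (enough)
    icc_absolute_agreement(pairs$manual_duration_s, pairs$auto_duration_s,
                           model = "mixed", log_transform = TRUE,
                           conf_level = conf_level) else NULL
  bias <- if (nrow(pairs) >= 1)
    bias_percentiles(pairs$auto_duration_s, pairs$manual_duration_s,
                     window_s = detection$params$window_s) else NULL

  structure(list(counts = counts, metrics = metrics,
                 rho = rho, icc = icc, bias = bias,
                 n_periods_manual = n_manual, n_periods_auto = n_auto,
                 n_matched = nrow(pairs), period_level = level,
                 pairs = pairs,
                 difference_sign = "automated - manual",
                 params = detection$params),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  d <- x$metrics$display
  cat("Criterion validity of the automated live-play detection\n")
  cat(sprintf("  accuracy %.1f%%  misclassification %.1f%%  precision %.1f%%  sensitivity %.1f%%\n",
              d$accuracy, d$misclassification, d$precision, d$sensitivity))
  cat(sprintf("  periods (%s level): manual %d, automated %d, matched %d\n",
              x$period_level, x$n_periods_manual, x$n_periods_auto, x$n_matched))
  if (!is.null(x$rho))
    cat(sprintf("  Spearman rho = %.3f (%s), p = %.3g\n",
                x$rho$rho, x$rho$band, x$rho$p))
  if (!is.null(x$icc))
    cat(sprintf("  ICC(A,1)%s = %.3f (95%% CI %.3f-%.3f, %s)\n",
                if (x$icc$log_transformed) " on log durations" else "",
                x$icc$icc, x$icc$ci_low, x$icc$ci_high, x$icc$band))
  if (!is.null(x$bias))
    cat(sprintf("  bias (%s): median %g s (%g to %g s)%s\n", x$difference_sign,
                x$bias$median, x$bias$p5, x$bias$p95,
                if (isTRUE(x$bias$within_two_windows))
                  ", within two sample windows" else ""))
  invisible(x)
}

#' Flatten an agreement report for JSON export
#'
#' @param report An [evaluate_agreement()] result.
#' @return A plain named list suitable for [write_report()].
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  list(
    counts = unclass(report$counts),
    accuracy_pct = report$metrics$accuracy,
    misclassification_pct = report$metrics$misclassification,
    precision_pct = report$metrics$precision,
    sensitivity_pct = report$metrics$sensitivity,
    spearman_rho = if (!is.null(report$rho)) report$rho$rho else NA,
    spearman_p = if (!is.null(report$rho)) report$rho$p else NA,
    icc = if (!is.null(report$icc)) report$icc$icc else NA,
    icc_ci_low = if (!is.null(report$icc)) report$icc$ci_low else NA,
    icc_ci_high = if (!is.null(report$icc)) report$icc$ci_high else NA,
    median_bias_s = if (!is.null(report$bias)) report$bias$median else NA,
    bias_p5_s = if (!is.null(report$bias)) report$bias$p5 else NA,
    bias_p95_s = if (!is.null(report$bias)) report$bias$p95 else NA,
    n_periods_manual = report$n_periods_manual,
    n_periods_auto = report$n_periods_auto,
    n_matched = report$n_matched,
    period_level = report$period_level,
    difference_sign = report$difference_sign)
}
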