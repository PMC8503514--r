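# Independent brute-force reference implementations used as oracles.
# Deliberately naive (explicit loops, direct formulas) and kept free of any
# code path from the package itself.

brute_moving_average <- function(x, w) {
  n <- length(x)
  left <- w %/% 2
  right <- w - 1 - left
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - left):min(n, i + right)
    mean(x[idx])
  }, numeric(1))
}

brute_fill_gaps <- function(mask, min_gap) {
  n <- length(mask)
  out <- mask
  i <- 1
  while (i <= n) {
    if (!mask[i]) {
      j <- i
      while (j < n && !mask[j + 1]) j <- j + 1
      run_len <- j - i + 1
      flanked <- i > 1 && j < n   # active on both sides by maximality
      if (flanked && run_len < min_gap) out[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  out
}

brute_team_rule <- function(m, k) {
  out <- m
  for (t in seq_len(nrow(m)))
    if (sum(m[t, ]) <= k - 1) out[t, ] <- FALSE
  out
}

brute_segment <- function(mask) {
  starts <- c(); ends <- c()
  n <- length(mask)
  inside <- FALSE
  for (t in seq_len(n)) {
    if (mask[t] && !inside) { starts <- c(starts, t - 1); inside <- TRUE }
    if (!mask[t] && inside) { ends <- c(ends, t - 1); inside <- FALSE }
  }
  if (inside) ends <- c(ends, n)
  data.frame(start_s = starts %||% integer(0), end_s = ends %||% integer(0))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

brute_confusion <- function(auto, manual) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(auto)) {
    if (manual[i] && auto[i]) tp <- tp + 1
    else if (manual[i] && !auto[i]) fn <- fn + 1
    else if (!manual[i] && auto[i]) fp <- fp + 1
    else tn <- tn + 1
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Linear-interpolation quantile (type 7), from the definition.
brute_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  frac <- h - lo
  s[lo + 1] + frac * (ifelse(lo + 2 > n, s[n], s[pmin(n, lo + 2)]) - s[lo + 1])
}

# ICC(A,1) from scratch: explicit two-way ANOVA sums of squares.
brute_icc_a1 <- function(x, y) {
  dat <- cbind(x, y)
  n <- nrow(dat); k <- 2
  grand <- mean(dat)
  ss_total <- sum((dat - grand)^2)
  ss_rows <- k * sum((rowMeans(dat) - grand)^2)
  ss_cols <- n * sum((colMeans(dat) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Same decomposition routed through base R's linear-model ANOVA instead of
# explicit sums, as a second independent path to the mean squares.
aov_icc_a1 <- function(x, y) {
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_along(x), 2)),
                  rater = factor(rep(1:2, each = length(x))))
  ms <- anova(lm(value ~ subject + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- length(x); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# The documented greedy max-overlap pairing rule, re-implemented directly on
# second sets rather than interval arithmetic.
brute_match <- function(man, aut) {
  seconds <- function(s, e) if (e > s) seq(s, e - 1) else integer(0)
  used <- rep(FALSE, nrow(aut))
  pairs <- list()
  for (i in seq_len(nrow(man))) {
    msec <- seconds(man$start_s[i], man$end_s[i])
    best_j <- 0; best_ov <- 0
    for (j in seq_len(nrow(aut))) {
      if (used[j]) next
      ov <- length(intersect(msec, seconds(aut$start_s[j], aut$end_s[j])))
      if (ov > best_ov) { best_ov <- ov; best_j <- j }
    }
    if (best_j > 0) {
      used[best_j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, best_j, best_ov)
    }
  }
  do.call(rbind, pairs)
}

# Random boolean mask with realistic run structure.
random_mask <- function(n, p_switch = 0.08) {
  state <- runif(1) < 0.5
  out <- logical(n)
  for (i in seq_len(n)) {
    if (runif(1) < p_switch) state <- !state
    out[i] <- state
  }
  out
}

# Random sorted non-overlapping period list on [0, horizon).
random_periods <- function(n_periods, horizon) {
  if (n_periods == 0)
    return(data.frame(start_s = integer(0), end_s = integer(0)))
  cuts <- sort(sample(0:horizon, 2 * n_periods))
  data.frame(start_s = cuts[seq(1, 2 * n_periods, 2)],
             end_s = cuts[seq(2, 2 * n_periods, 2)] + 1)
}

# Small simulated match at reduced scale, for fast end-to-end checks.
small_sim <- function(seed, ...) {
  p <- simulation_params(match_end_s = 1800, half_time_s = 300,
                         roster_size = 8, ...)
  simulate_match(p, seed = seed)
}
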