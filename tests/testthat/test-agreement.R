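test_that("confusion counts tabulate trivial and random mask pairs", {
  set.seed(60)
  m <- matrix(random_mask(200 * 3, 0.1), 200, 3)
  cc <- confusion_counts(m, m)
  expect_equal(cc$tp, sum(m)); expect_equal(cc$tn, sum(!m))
  expect_equal(cc$fp + cc$fn, 0)

  all_on <- matrix(TRUE, 50, 2); all_off <- matrix(FALSE, 50, 2)
  cc2 <- confusion_counts(all_off, all_on)     # manual active, auto inactive
  expect_equal(unlist(unclass(cc2)), c(tp = 0, fn = 100, fp = 0, tn = 0))

  for (i in 1:40) {
    a <- runif(150) < 0.5; b <- runif(150) < 0.5
    got <- confusion_counts(matrix(a), matrix(b))
    want <- brute_confusion(a, b)
    expect_equal(unlist(unclass(got)), want)
    expect_equal(got$tp + got$fn + got$fp + got$tn, 150)
  }
})

test_that("confusion counts are invariant to player permutation", {
  set.seed(61)
  a <- matrix(runif(300) < 0.4, 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  m <- matrix(runif(300) < 0.4, 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  c1 <- confusion_counts(a, m)
  perm <- c("C", "A", "B")
  c2 <- confusion_counts(a[, perm], m[, perm])
  expect_identical(unclass(c1), unclass(c2))
})

test_that("classification metrics reproduce published-scale counts and edge cases", {
  m <- classification_metrics(list(tp = 23275, fn = 3047, fp = 2306, tn = 75367))
  expect_equal(m$display$accuracy, 94.9)
  expect_equal(m$display$misclassification, 5.1)
  expect_equal(m$display$precision, 91.0)
  expect_equal(m$display$sensitivity, 88.4)
  expect_equal(m$accuracy + m$misclassification, 100)     # exact, pre-rounding

  p <- classification_metrics(list(tp = 37, fn = 0, fp = 0, tn = 112))
  expect_equal(unlist(p[c("accuracy", "misclassification", "precision",
                          "sensitivity")]),
               c(accuracy = 100, misclassification = 0, precision = 100,
                 sensitivity = 100))

  und <- classification_metrics(list(tp = 0, fn = 5, fp = 0, tn = 10))
  expect_true(is.nan(und$precision))
  expect_false(is.nan(und$sensitivity))

  set.seed(62)
  for (i in 1:50) {
    k <- as.list(setNames(sample(0:500, 4, replace = TRUE),
                          c("tp", "fn", "fp", "tn")))
    if (sum(unlist(k)) == 0) next
    g <- classification_metrics(k)
    tot <- k$tp + k$fn + k$fp + k$tn
    expect_equal(g$accuracy, 100 * (k$tp + k$tn) / tot, tolerance = 1e-12)
    expect_equal(g$accuracy + g$misclassification, 100, tolerance = 0)
    if (k$tp + k$fp > 0)
      expect_equal(g$precision, 100 * k$tp / (k$tp + k$fp), tolerance = 1e-12)
    if (k$tp + k$fn > 0)
      expect_equal(g$sensitivity, 100 * k$tp / (k$tp + k$fn), tolerance = 1e-12)
  }
})

test_that("period matching pairs by maximal overlap with greedy manual order", {
  man <- data.frame(start_s = c(10, 50), end_s = c(30, 120))
  mm <- match_periods(man, man)
  expect_equal(nrow(mm$pairs), 2)
  expect_equal(nrow(mm$unmatched_manual), 0)
  expect_equal(nrow(mm$unmatched_auto), 0)

  aut <- data.frame(start_s = c(12, 40), end_s = c(28, 50))
  mp <- match_periods(data.frame(start_s = 10, end_s = 30), aut)
  expect_equal(mp$pairs$auto_start_s, 12)
  expect_equal(mp$pairs$overlap_s, 16)
  expect_equal(mp$unmatched_auto$start_s, 40)

  set.seed(63)
  for (i in 1:50) {
    man <- random_periods(sample(0:8, 1), 120)
    aut <- random_periods(sample(0:8, 1), 120)
    got <- match_periods(man, aut)
    want <- brute_match(man, aut)
    if (is.null(want)) {
      expect_equal(nrow(got$pairs), 0)
    } else {
      expect_equal(nrow(got$pairs), nrow(want))
      expect_equal(got$pairs$manual_start_s, man$start_s[want[, 1]])
      expect_equal(got$pairs$auto_start_s, aut$start_s[want[, 2]])
      expect_equal(got$pairs$overlap_s, want[, 3])
    }
  }
})

test_that("Spearman's rho matches oracles and handles monotone extremes", {
  x <- c(3, 9, 12, 20, 44)
  expect_equal(spearman_rho(x, x^2 + 1)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  expect_equal(spearman_rho(x, x^2 + 1)$p, 0)
  expect_warning(r0 <- spearman_rho(rep(4, 6), x = 1:6), "constant")
  expect_true(is.na(r0$rho))

  set.seed(64)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- spearman_rho(x, y)
    expect_equal(got$rho, brute_spearman(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-9)
  }
  # average ranks for ties
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 9, 7, 8)
  expect_equal(spearman_rho(xt, yt)$rho, brute_spearman(xt, yt), tolerance = 1e-12)
})

test_that("rho qualitative bands follow the published scale", {
  expect_equal(spearman_rho(1:20, 1:20)$band, "nearly perfect")
  set.seed(65)
  x <- rnorm(200); y <- x + rnorm(200, sd = 0.55)
  expect_true(spearman_rho(x, y)$band %in% c("large", "very large"))
})

test_that("ICC(A,1) agrees with ANOVA oracles to 1e-10", {
  set.seed(66)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    subj <- exp(rnorm(n, 3, 0.8))
    x <- subj * exp(rnorm(n, 0, 0.2)) + 1
    y <- subj * exp(rnorm(n, 0.05, 0.2)) + 1
    got <- icc_absolute_agreement(x, y, log_transform = TRUE)
    lx <- log(x); ly <- log(y)
    expect_equal(got$icc, brute_icc_a1(lx, ly), tolerance = 1e-10)
    expect_equal(got$icc, aov_icc_a1(lx, ly), tolerance = 1e-10)
    expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
    # absolute agreement cannot exceed consistency whenever the between-method
    # variance is at least the residual variance (it ties or reverses only
    # when the method effect is below noise)
    if (got$msc >= got$mse) expect_lte(got$icc, got$icc_consistency + 1e-12)
  }
  # with a genuine systematic offset the inequality is strict
  set.seed(660)
  x <- exp(rnorm(30, 3, 0.5)) + 1
  strict <- icc_absolute_agreement(x, x * 1.4, log_transform = TRUE)
  expect_lt(strict$icc, strict$icc_consistency)
})

test_that("ICC distinguishes identity from systematic offset", {
  x <- c(5, 9, 14, 22, 31, 47, 60, 75)
  ident <- icc_absolute_agreement(x, x, log_transform = FALSE)
  expect_equal(ident$icc, 1)
  expect_equal(ident$band, "excellent")

  off <- icc_absolute_agreement(x, x + 40, log_transform = FALSE)
  expect_lt(off$icc, 0.6)                          # offsets are penalised
  expect_equal(off$icc_consistency, 1, tolerance = 1e-12)

  expect_warning(flat <- icc_absolute_agreement(rep(3, 6), rep(3, 6),
                                                log_transform = FALSE),
                 "no between-subject variance")
  expect_true(is.na(flat$icc))
  expect_error(icc_absolute_agreement(c(0.5, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
               "log transform")
})

test_that("ICC confidence interval matches a reference computation", {
  # reference interval computed independently from the McGraw & Wong
  # F-based formulas using a spreadsheet-style step-by-step evaluation
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  got <- icc_absolute_agreement(x, y, log_transform = FALSE)
  n <- 6; k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  msr <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(dat) - grand)^2) / (k - 1)
  mse <- (sum((dat - grand)^2) - k * sum((rowMeans(dat) - grand)^2) -
            n * sum((colMeans(dat) - grand)^2)) / ((n - 1) * (k - 1))
  icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$icc, icc_ref, tolerance = 1e-12)
  a <- k * icc_ref / (n * (1 - icc_ref))
  b <- 1 + k * icc_ref * (n - 1) / (n * (1 - icc_ref))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(0.975, n - 1, v); fu <- qf(0.975, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  expect_equal(got$ci_low, lo, tolerance = 1e-10)
  expect_equal(got$ci_high, hi, tolerance = 1e-10)
})

test_that("bias percentiles match the sort-based quantile oracle", {
  expect_equal(unlist(bias_percentiles(c(10, 20, 30), c(10, 20, 30))[1:3]),
               c(median = 0, p5 = 0, p95 = 0))
  d <- c(-5, -1, 0, 2, 4)
  expect_equal(bias_percentiles(d, rep(0, 5))$median, 0)

  set.seed(67)
  for (i in 1:20) {
    a <- sample(5:120, 200, replace = TRUE)
    m <- sample(5:120, 200, replace = TRUE)
    got <- bias_percentiles(a, m, window_s = 9)
    d <- a - m
    expect_equal(got$median, brute_quantile7(d, 0.5), tolerance = 1e-12)
    expect_equal(got$p5, brute_quantile7(d, 0.05), tolerance = 1e-12)
    expect_equal(got$p95, brute_quantile7(d, 0.95), tolerance = 1e-12)
    expect_equal(got$within_two_windows, max(abs(c(got$p5, got$p95))) < 18)
  }
})

test_that("statistics are invariant to the order of period pairs", {
  set.seed(68)
  x <- exp(rnorm(30, 3.5, 0.6)); y <- x * exp(rnorm(30, 0, 0.1))
  perm <- sample(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(x[perm], y[perm])$rho)
  expect_equal(icc_absolute_agreement(x + 1, y + 1)$icc,
               icc_absolute_agreement(x[perm] + 1, y[perm] + 1)$icc)
  expect_equal(bias_percentiles(y, x)[1:3],
               bias_percentiles(y[perm], x[perm])[1:3])
})

test_that("perfect agreement is a fixed point of the full evaluation", {
  sim <- small_sim(69)
  det <- detect_live_play(sim$intensity, sim$config)
  # evaluate the automated output against itself as criterion
  rep <- evaluate_agreement(det, manual_player_masks = det$player_masks)
  expect_equal(rep$metrics$accuracy, 100)
  expect_equal(rep$metrics$misclassification, 0)
  expect_equal(rep$rho$rho, 1)
  expect_equal(rep$icc$icc, 1, tolerance = 1e-12)
  expect_equal(unlist(rep$bias[c("median", "p5", "p95")]),
               c(median = 0, p5 = 0, p95 = 0))
  expect_equal(rep$n_matched, rep$n_periods_manual)
})

test_that("evaluation against ground truth reports a coherent full battery", {
  sim <- small_sim(70)
  det <- detect_live_play(sim$intensity, sim$config)
  rep <- evaluate_agreement(det, manual_periods = sim$annotations,
                            manual_player_masks = sim$truth_masks)
  expect_gt(rep$metrics$accuracy, 90)
  expect_equal(rep$metrics$accuracy + rep$metrics$misclassification, 100)
  expect_equal(rep$period_level, "player")
  expect_gt(rep$rho$rho, 0.8)
  expect_true(rep$icc$log_transformed)
  expect_lte(rep$n_matched, min(rep$n_periods_manual, rep$n_periods_auto))
  lst <- report_as_list(rep)
  expect_equal(lst$accuracy_pct, rep$metrics$accuracy)
  f <- tempfile(fileext = ".json")
  write_report(lst, f)
  expect_equal(read_report(f)$icc, rep$icc$icc, tolerance = 1e-12)
})

test_that("team-level evaluation works from annotations alone", {
  sim <- small_sim(71)
  det <- detect_live_play(sim$intensity, sim$config)
  rep <- evaluate_agreement(det, manual_periods = sim$annotations)
  expect_equal(rep$period_level, "team")
  expect_equal(rep$n_periods_manual, nrow(sim$annotations))
})
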