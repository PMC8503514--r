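test_that("score_parameters counts agreeing player-seconds", {
  set.seed(50)
  m <- matrix(random_mask(100 * 4, 0.2), 100, 4)
  expect_equal(score_parameters(m, m)$proportion, 1)
  expect_equal(score_parameters(m, !m)$proportion, 0)

  set.seed(51)
  for (i in 1:30) {
    a <- matrix(runif(50 * 3) < 0.5, 50, 3)
    b <- matrix(runif(50 * 3) < 0.5, 50, 3)
    got <- score_parameters(a, b)
    expect_equal(got$correct, sum(a == b))
    expect_equal(got$total, 150)
    # symmetry and joint player permutation
    expect_equal(score_parameters(b, a)$correct, got$correct)
    perm <- sample(3)
    expect_equal(score_parameters(a[, perm], b[, perm])$correct, got$correct)
  }
  expect_error(score_parameters(matrix(TRUE, 5, 2), matrix(TRUE, 6, 2)),
               "dimensions differ")
})

test_that("grid search scores every default cell and finds nothing in quiet data", {
  cfg <- match_config(
    players = data.frame(player_id = "P1", mass_kg = 85, slope = 1, intercept = 0),
    match_end_s = 300, detector = detector_params(min_players_active = 1))
  quiet <- list(P1 = intensity_series(rep(3, 300)))
  set.seed(52)
  manual <- matrix(random_mask(300), 300, 1, dimnames = list(NULL, "P1"))
  g <- grid_search(list(intensity = quiet, manual_masks = manual, config = cfg))
  expect_equal(nrow(g), 25)                                # 5 x 5 default grid
  expect_true(all(g$score == mean(!manual)))               # detector finds nothing
  expect_error(grid_search(list(intensity = quiet, manual_masks = manual,
                                config = cfg), windows_s = 5),
               "at least two")
})

test_that("surface fit recovers an exact quadratic and flags degeneracy", {
  grid <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                      threshold_pct = c(20, 25, 30, 35, 40))
  b_true <- c(0.2, 0.01, 0.02, -0.003, -0.0005, 0.0008)
  grid$score <- b_true[1] + b_true[2] * grid$window_s + b_true[3] * grid$threshold_pct +
    b_true[4] * grid$window_s^2 + b_true[5] * grid$threshold_pct^2 +
    b_true[6] * grid$window_s * grid$threshold_pct
  m <- fit_quadratic_surface(grid)
  expect_equal(unname(m$coefficients), b_true, tolerance = 1e-8)
  expect_equal(m$fit_r, 1, tolerance = 1e-10)

  const <- grid; const$score <- 0.5
  expect_warning(mc <- fit_quadratic_surface(const), "constant scores")
  expect_true(is.nan(mc$fit_r))
  expect_equal(unname(mc$coefficients[2:6]), rep(0, 5), tolerance = 1e-10)

  one_w <- grid[grid$window_s == 5, ]
  expect_error(fit_quadratic_surface(one_w), "at least 6")
  one_w6 <- rbind(one_w, one_w)   # enough cells but a single window value
  expect_error(fit_quadratic_surface(one_w6), "rank-deficient")
})

test_that("noisy surface fit equals the normal-equations oracle", {
  set.seed(53)
  grid <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                      threshold_pct = c(20, 25, 30, 35, 40))
  for (i in 1:20) {
    grid$score <- runif(25)
    m <- fit_quadratic_surface(grid)
    X <- with(grid, cbind(1, window_s, threshold_pct, window_s^2,
                          threshold_pct^2, window_s * threshold_pct))
    beta <- solve(t(X) %*% X, t(X) %*% grid$score)
    expect_equal(unname(m$coefficients), as.numeric(beta), tolerance = 1e-8)
    fitted <- as.numeric(X %*% beta)
    expect_equal(m$fit_r, cor(fitted, grid$score), tolerance = 1e-10)
    expect_lt(m$fit_r, 1)
  }
})

test_that("surface optimisation finds interior, boundary and degenerate optima", {
  grid <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                      threshold_pct = c(20, 25, 30, 35, 40))
  # concave paraboloid with its peak at (9, 31)
  grid$score <- 100 - (grid$window_s - 9)^2 - (grid$threshold_pct - 31)^2
  opt <- optimize_surface(fit_quadratic_surface(grid))
  expect_equal(opt$window_s, 9, tolerance = 1e-6)
  expect_equal(opt$threshold_pct, 31, tolerance = 1e-6)
  expect_equal(opt$source, "analytic")
  expect_equal(opt$window_s_int, 9L)
  expect_equal(opt$threshold_pct_int, 31L)

  # linear ramp: no interior optimum, best corner is (25, 40)
  lin <- grid; lin$score <- lin$window_s + lin$threshold_pct
  opt_lin <- optimize_surface(fit_quadratic_surface(lin))
  expect_equal(opt_lin$window_s, 25, tolerance = 1e-6)
  expect_equal(opt_lin$threshold_pct, 40, tolerance = 1e-6)
  expect_equal(opt_lin$source, "clamped")
})

test_that("random concave quadratics match a dense-lattice arg-max", {
  set.seed(54)
  grid_pts <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                          threshold_pct = c(20, 25, 30, 35, 40))
  for (i in 1:25) {
    # random negative-definite Hessian
    h11 <- -runif(1, 0.001, 0.01)
    h22 <- -runif(1, 0.001, 0.01)
    h12 <- runif(1, -1, 1) * sqrt(h11 * h22) * 0.9
    b1 <- runif(1, -0.2, 0.2); b2 <- runif(1, -0.2, 0.2)
    f <- function(W, T) b1 * W + b2 * T + 0.5 * h11 * W^2 + 0.5 * h22 * T^2 + h12 * W * T
    g <- grid_pts
    g$score <- f(g$window_s, g$threshold_pct)
    opt <- optimize_surface(fit_quadratic_surface(g))
    lat <- expand.grid(W = seq(5, 25, by = 0.01), T = seq(20, 40, by = 0.05))
    best <- lat[which.max(f(lat$W, lat$T)), ]
    expect_lt(abs(opt$window_s - best$W), 0.011)
    expect_lt(abs(opt$threshold_pct - best$T), 0.051)
  }
})

test_that("fit-then-optimise recovers planted optima under noise", {
  set.seed(55)
  grid_pts <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                          threshold_pct = c(20, 25, 30, 35, 40))
  hits <- 0
  n_rep <- 200
  for (i in 1:n_rep) {
    w0 <- runif(1, 7, 23); t0 <- runif(1, 23, 37)
    g <- grid_pts
    g$score <- 1 - 0.002 * (g$window_s - w0)^2 - 0.002 * (g$threshold_pct - t0)^2 +
      rnorm(25, sd = 0.005)
    opt <- optimize_surface(fit_quadratic_surface(g))
    if (abs(opt$window_s - w0) <= 5 && abs(opt$threshold_pct - t0) <= 5)
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("sensitivity table quantifies the near-flat maximum", {
  grid <- expand.grid(window_s = c(5, 10, 15, 20, 25),
                      threshold_pct = c(20, 25, 30, 35, 40))
  grid$score <- 0.95 - 1e-4 * (grid$window_s - 9)^2 - 1e-4 * (grid$threshold_pct - 31)^2
  m <- fit_quadratic_surface(grid)
  st <- sensitivity_table(m)
  expect_lt(st$surface_pct_change, 0.9)   # blunt peak: sub-percent variation
  expect_true(is.finite(st$grid_pct_change))
})
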