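test_that("the default window layout gives five 1-s windows at 50% overlap", {
  w <- make_windows(500)
  expect_equal(nrow(w), 5)
  expect_equal(w$t_start, c(-2, -1.5, -1, -0.5, 0))
  expect_equal(w$t_end, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(w$end_sample - w$start_sample, rep(500L, 5))
  expect_equal(w$start_sample, c(0L, 250L, 500L, 750L, 1000L))
  expect_equal(w$end_sample[5], 1500L)  # last window ends at the epoch end
})

test_that("window layout handles degenerate geometries", {
  one <- make_windows(500, c(-2, 1), window_length = 3, overlap = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$end_sample - one$start_sample, 1500L)

  disjoint <- make_windows(500, c(-2, 1), window_length = 1, overlap = 0)
  expect_equal(nrow(disjoint), 3)
  expect_equal(disjoint$start_sample, c(0L, 500L, 1000L))

  expect_error(make_windows(500, c(-2, 1), overlap = 1), "step")
  expect_error(make_windows(500, c(-1, 0), window_length = 2), "exceeds epoch")
})

test_that("AIC is n ln(RSS/n) + 2k exactly", {
  expect_equal(aic(100, 100, 5), 10)
  expect_equal(aic(500, 50, 24), 500 * log(0.1) + 48)
  expect_equal(aic(200, 17, 10) - aic(200, 17, 0), 20)  # linear in k
  expect_error(aic(100, 0, 2), "positive")
})

test_that("AR least squares recovers known coefficients", {
  set.seed(1)
  x <- rnorm(5000)
  f <- fit_ar(x, x, p = 1)
  expect_lt(abs(f$coefficients[1, 1]), 0.05)
  expect_equal(f$residual_variance, var(x), tolerance = 0.05)
  expect_equal(f$rss / f$n_obs, f$residual_variance)

  y <- as.numeric(stats::filter(rnorm(5000), 0.9, method = "recursive"))
  f2 <- fit_ar(y, y, p = 1)
  expect_lt(abs(f2$coefficients[1, 1] - 0.9), 0.05)
  # residuals orthogonal to the design
  expect_lt(abs(sum(f2$residuals * y[1:(5000 - 1)])) / f2$rss, 1e-8)

  expect_error(fit_ar(x, cbind(x, x), p = 2), "rank-deficient")
  expect_error(fit_ar(rep(1, 100), rep(1, 100), p = 2), "rank-deficient")
})

test_that("gc_pair recovers a planted direction", {
  set.seed(2)
  hits <- 0
  for (s in 1:200) {
    y <- rnorm(500)
    x <- 0.6 * c(0, y[-500]) + rnorm(500)
    f <- gc_pair(x, y, p = 5)
    if (f["y_to_x"] > f["x_to_y"]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("null gc bias matches an independent lm-based oracle", {
  set.seed(3)
  n_sim <- 120
  ours <- numeric(n_sim)
  oracle <- numeric(n_sim)
  for (s in 1:n_sim) {
    x <- rnorm(500); y <- rnorm(500)
    ours[s] <- gc_pair(x, y, p = 12)["y_to_x"]
    x2 <- rnorm(500); y2 <- rnorm(500)
    oracle[s] <- naive_gc_pair(x2, y2, p = 12)["y_to_x"]
  }
  se <- sqrt(var(ours) / n_sim + var(oracle) / n_sim)
  expect_lt(abs(mean(ours) - mean(oracle)), 3 * se)
})

test_that("gc_pair matches the naive oracle to 1e-8 on identical data", {
  set.seed(4)
  for (s in 1:5) {
    x <- rnorm(300); y <- 0.4 * c(0, 0, x[1:298]) + rnorm(300)
    expect_equal(unclass(gc_pair(x, y, 4))[1:2],
                 naive_gc_pair(x, y, 4), tolerance = 1e-8)
  }
})

test_that("gc_matrix matches per-pair oracle values on a 3-channel system", {
  set.seed(5)
  X <- matrix(rnorm(300 * 3), ncol = 3)
  X[, 2] <- X[, 2] + 0.5 * c(0, X[1:299, 1])
  W <- gc_matrix(t(X), p = 3)$weights
  for (i in 1:2) {
    for (j in (i + 1):3) {
      f <- naive_gc_pair(X[, i], X[, j], 3)
      expect_equal(W[j, i], unname(f["y_to_x"]), tolerance = 1e-8)
      expect_equal(W[i, j], unname(f["x_to_y"]), tolerance = 1e-8)
    }
  }
  expect_equal(diag(W), rep(0, 3))
  expect_equal(gc_matrix(t(X), 3)$symmetric_max, pmax(W, t(W)))
})

test_that("degenerate pairs fail loudly", {
  set.seed(6)
  x <- rnorm(200)
  expect_error(gc_pair(x, x, 3), "rank-deficient")
  expect_error(gc_matrix(array(rnorm(100), dim = c(1, 1, 100)), 3),
               "at least 2 channels")
})

test_that("gc is invariant to channel rescaling", {
  set.seed(7)
  X <- matrix(rnorm(400 * 3), ncol = 3)
  X[, 3] <- X[, 3] + 0.5 * c(0, X[1:399, 2])
  W1 <- gc_matrix(t(X), 4)$weights
  X2 <- X %*% diag(c(7, 0.01, 1000))
  W2 <- gc_matrix(t(X2), 4)$weights
  expect_equal(W1, W2, tolerance = 1e-6)
})

test_that("stronger planted coupling never weakens the estimated F", {
  set.seed(8)
  n <- 800
  innov_x <- rnorm(n); innov_y <- rnorm(n)
  f_at <- vapply(c(0.1, 0.2, 0.4, 0.8), function(cpl) {
    y <- innov_y
    x <- cpl * c(0, y[-n]) + innov_x  # same innovations across the grid
    gc_pair(x, y, 3)["y_to_x"]
  }, numeric(1))
  expect_true(all(diff(f_at) > 0))
})

test_that("order selection behaves on collapsed and simple searches", {
  g <- var3_pair_graph()
  X <- sim_graph(g, 2000, seed = 9)
  arr <- array(t(X), dim = c(1, 2, 2000))
  expect_equal(select_order(arr, p_range = 4, trial_subsample = 0)$p0, 4)

  # AR(1)-dominated pair: the trace should bottom out at a small order
  g1 <- ground_truth_graph(
    2, data.frame(source = 1, target = 2, magnitude = 0.5, lag = 1),
    self_coef = 0.5, order = 1)
  X1 <- sim_graph(g1, 4000, seed = 10)
  sel <- select_order(array(t(X1), dim = c(1, 2, 4000)), 1:5,
                      trial_subsample = 0)
  expect_lte(sel$p0, 2)
  expect_equal(nrow(sel$trace), 5)
  expect_error(select_order(array(rnorm(2 * 2 * 30), dim = c(2, 2, 30)), 1:15),
               "support")
})

test_that("order selection on an epoch set uses lead collision trials", {
  des <- session_design(n_trials = 8, n_channels = 3, n_subjects_per_group = 1,
                        trial_duration = 4, seed = 30)
  ses <- simulate_session(des)
  ep <- preprocess_session(ses, band = "beta", z_threshold = Inf)
  set.seed(31)
  sel <- select_order(ep, p_range = c(6, 12), n_lead_trials = 2,
                      trial_subsample = 0)
  expect_true(sel$p0 %in% c(6, 12))
  expect_equal(sel$trace$p, c(6, 12))
})

test_that("cell-wise gc produces one matrix per subject/condition/window", {
  des <- session_design(n_trials = 6, n_channels = 4, n_subjects_per_group = 1,
                        trial_duration = 4, seed = 32)
  ses <- simulate_session(des)
  ep <- preprocess_session(ses, band = "beta", z_threshold = Inf)
  res <- gc_cells(ep, p = 8)
  # 2 subjects x 2 conditions x 5 windows
  expect_equal(length(res$cells), 20)
  expect_equal(nrow(res$long), 20 * 4 * 3)  # 12 ordered pairs per cell
  expect_true(all(res$long$F >= -1e-10))
  expect_setequal(unique(res$long$window), paste0("SW", 1:5))
  expect_equal(unique(res$long$band), "beta")
})
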