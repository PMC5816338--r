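test_that("window selection discards the first second and spans the request", {
  tr <- sine_trace(duration = 20, fs = 100)
  w <- select_window(tr, 10)
  expect_equal(w$t[1], 0)
  expect_lt(max(w$t), 10)
  expect_equal(length(w$t), 1000L)  # samples with t in [1, 11)
  # original second 1 is the window's time zero
  expect_equal(w$head_vel[1], tr$head_vel[which(tr$t >= 1)[1]])

  short <- sine_trace(duration = 8, fs = 100)
  expect_warning(w2 <- select_window(short, 10), "full remainder")
  expect_equal(diff(range(w2$t)), 7, tolerance = 0.02)

  expect_error(select_window(sine_trace(duration = 1.5, fs = 100)),
               class = "vvor_tooshort_error")
})

test_that("gains on the 10-s window match gains on the full noiseless trace", {
  p <- synth_params(duration = 20, noise_sd = 0, freq_jitter = 0,
                    g_pos = 0.8, g_neg = 0.8, seed = 3)
  sim <- simulate_vvor(p)
  g_win <- auc_gain(desaccade(select_window(sim$trace)))
  g_full <- auc_gain(desaccade(sim$trace))
  expect_equal(g_win$g_pos, g_full$g_pos, tolerance = 0.01)
  expect_equal(g_win$g_neg, g_full$g_neg, tolerance = 0.01)
})

test_that("sign convention is an involution and swaps directional gains", {
  tr <- sine_trace()
  expect_equal(apply_sign_convention(tr, sign_convention())[c("head_vel", "eye_vel")],
               tr[c("head_vel", "eye_vel")])
  flip <- sign_convention(invert_head = TRUE)
  twice <- apply_sign_convention(apply_sign_convention(tr, flip), flip)
  expect_equal(twice$head_vel, tr$head_vel)

  sim <- simulate_vvor(vvor_preset("unilateral", seed = 5))
  d0 <- desaccade(select_window(sim$trace))
  g0 <- auc_gain(d0)
  flipped <- apply_sign_convention(sim$trace,
                                   sign_convention(invert_head = TRUE,
                                                   invert_eye = TRUE))
  g1 <- auc_gain(desaccade(select_window(flipped)))
  expect_equal(g1$g_pos, g0$g_neg, tolerance = 1e-10)
  expect_equal(g1$g_neg, g0$g_pos, tolerance = 1e-10)
})

test_that("median filter removes lone spikes but passes constants", {
  x <- rep(50, 200)
  tr <- velocity_trace(seq_along(x) / 100, sin(seq_along(x)), x,
                       sample_rate = 100)
  # zero-padding distorts only the edge transient; interior is exact
  d <- desaccade(tr)
  interior <- 31:170
  expect_equal(d$eye_filtered[interior], rep(50, 140))
  expect_equal(d$residual[interior], rep(0, 140))
  # reflection padding preserves constants everywhere, any n
  for (n in c(5, 30)) {
    dr <- desaccade(tr, desaccade_params(n, "reflect"))
    expect_equal(dr$eye_filtered, rep(50, 200))
    expect_equal(dr$residual, rep(0, 200))
  }

  y <- rep(0, 200); y[100] <- 300
  d2 <- desaccade(velocity_trace(seq_along(y) / 100, sin(seq_along(y)), y,
                                 sample_rate = 100))
  expect_equal(d2$eye_filtered, rep(0, 200))
  expect_equal(d2$residual[100], 300)
})

test_that("median filter matches the brute-force windowed median", {
  set.seed(42)
  x <- rnorm(200, sd = 50)
  for (n in c(4, 7, 30)) for (mode in c("zero-pad", "reflect")) {
    expect_equal(median_filter_1d(x, n, mode), brute_median_filter(x, n, mode),
                 tolerance = 1e-12,
                 label = sprintf("n=%d mode=%s", n, mode))
  }
})

test_that("filter output stays inside the raw range of each interior window", {
  set.seed(7)
  x <- rnorm(300, sd = 30)
  y <- median_filter_1d(x, 30)
  for (i in seq(40, 260, by = 13)) {
    w <- x[(i - 15):(i + 14)]
    expect_gte(y[i], min(w)); expect_lte(y[i], max(w))
  }
})

test_that("filter is shift-equivariant and monotone", {
  set.seed(8)
  x <- rnorm(150)
  # adding a constant shifts the output by that constant (interior; the
  # zero-pad edge breaks shift equivariance, reflect mode preserves it)
  expect_equal(median_filter_1d(x + 3, 15, "reflect"),
               median_filter_1d(x, 15, "reflect") + 3, tolerance = 1e-12)
  xp <- x + abs(rnorm(150))
  expect_true(all(median_filter_1d(xp, 15) >= median_filter_1d(x, 15)))
})

test_that("residual on a saccade-free protocol sinusoid is a small peak-smoothing artifact", {
  # 30-sample window at 220 Hz on a 1.5 Hz sinusoid: the windowed median
  # flattens the velocity peaks by ~5% of the amplitude and nothing more
  tr <- sine_trace(duration = 10, fs = 220, freq = 1.5, peak = 100)
  d <- desaccade(tr)
  interior <- 40:(length(tr$t) - 40)
  expect_lt(max(abs(d$residual[interior])), 6)
  # and well below any plausible saccade threshold
  expect_lt(max(abs(d$residual[interior])), 30)
})

test_that("filter parameter validation", {
  expect_error(desaccade_params(n = 2), class = "vvor_parameter_error")
  expect_error(desaccade(sine_trace(duration = 2.5, fs = 10),
                         desaccade_params(n = 30)),
               class = "vvor_parameter_error")
})
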