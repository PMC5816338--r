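test_that("directional split matches an elementwise sign test and drops zeros", {
  tr <- sine_trace(duration = 10, fs = 100, freq = 1)
  d <- identity_desaccaded(tr)
  dirs <- split_directions(d)
  pos <- sort(unlist(dirs$pos_runs)); neg <- sort(unlist(dirs$neg_runs))
  expect_true(all(tr$head_vel[pos] > 0))
  expect_true(all(tr$head_vel[neg] < 0))
  # alternating runs each covering about half the cycle
  expect_equal(length(dirs$pos_runs), 10, tolerance = 1)
  # every sample outside both subsets has head velocity exactly zero
  missing <- setdiff(seq_along(tr$t), c(pos, neg))
  expect_true(all(tr$head_vel[missing] == 0))

  allpos <- velocity_trace(1:100 / 10, abs(sin(1:100 / 5)) + 1, rnorm(100),
                           sample_rate = 10)
  expect_error(split_directions(identity_desaccaded(allpos)),
               "negative", class = "vvor_degenerate_error")
})

test_that("perfect and scaled compensation give exact AUC and slope gains", {
  tr <- sine_trace(duration = 10, fs = 100, freq = 1.3, peak = 120, gain = 1)
  d <- identity_desaccaded(tr)
  g <- auc_gain(d)
  expect_equal(g$g_pos, 1.0, tolerance = 1e-12)
  expect_equal(g$g_neg, 1.0, tolerance = 1e-12)
  s <- scp_gain(d)
  expect_equal(s$g_pos, 1.0, tolerance = 1e-12)
  expect_equal(s$g_neg, 1.0, tolerance = 1e-12)

  half <- identity_desaccaded(tr, eye_filtered = -0.5 * tr$head_vel)
  expect_equal(auc_gain(half)$g_pos, 0.5, tolerance = 1e-12)
  expect_equal(auc_gain(half)$g_neg, 0.5, tolerance = 1e-12)
})

test_that("AUC gain equals the hand-computed trapezoid ratio on a toy run", {
  # one positive run and one mirrored negative run; hand-computed integrals:
  # trapz(head) = 15.75, trapz(eye) = -12.6, gain = 12.6/15.75 = 0.8
  t <- 0:6
  h <- c(1, 3, 5, 4, 2, 1, 0.5)
  e <- c(-0.8, -2.1, -4.4, -3.1, -1.9, -0.6, -0.2)
  tr <- velocity_trace(c(t, t + 7), c(h, -h), c(e, -e), sample_rate = 1)
  d <- identity_desaccaded(tr)
  g <- auc_gain(d)
  expect_equal(g$g_pos, 0.8, tolerance = 1e-12)
  expect_equal(g$g_neg, 0.8, tolerance = 1e-12)
  # against the independent loop integrator
  expect_equal(g$g_pos, -brute_trapz(t, e) / brute_trapz(t, h),
               tolerance = 1e-12)
})

test_that("slope gain matches the closed-form least squares under noise", {
  set.seed(99)
  tr <- sine_trace(duration = 10, fs = 100, freq = 1, peak = 100)
  noisy_eye <- -0.8 * tr$head_vel + rnorm(length(tr$t), sd = 2)
  d <- identity_desaccaded(tr, eye_filtered = noisy_eye)
  s <- scp_gain(d)
  expect_equal(s$g_pos, 0.8, tolerance = 0.02)
  expect_equal(s$g_neg, 0.8, tolerance = 0.02)
  # exact agreement with the normal-equation solution per direction
  pos <- unlist(split_directions(d)$pos_runs)
  expect_equal(s$g_pos, -sum(tr$head_vel[pos] * noisy_eye[pos]) /
                 sum(tr$head_vel[pos]^2), tolerance = 1e-12)
})

test_that("anti-compensatory responses report negative gain, not clipped", {
  tr <- sine_trace(duration = 10, fs = 100)
  d <- identity_desaccaded(tr, eye_filtered = 0.3 * tr$head_vel)
  expect_equal(auc_gain(d)$g_pos, -0.3, tolerance = 1e-12)
  expect_equal(scp_gain(d)$g_neg, -0.3, tolerance = 1e-12)
})

test_that("both gain methods are invariant to a common positive rescaling", {
  sim <- simulate_vvor(vvor_preset("bilateral", seed = 13))
  d <- desaccade(select_window(sim$trace))
  scaled <- d
  scaled$base$head_vel <- 3.7 * d$base$head_vel
  scaled$eye_filtered <- 3.7 * d$eye_filtered
  expect_equal(auc_gain(scaled)$g_pos, auc_gain(d)$g_pos, tolerance = 1e-12)
  expect_equal(scp_gain(scaled)$g_neg, scp_gain(d)$g_neg, tolerance = 1e-12)
})

test_that("noiseless linear responses give identical AUC and slope gains", {
  tr <- sine_trace(duration = 10, fs = 220, freq = 1.5, peak = 150)
  for (g in c(0.1, 0.45, 0.8, 1.0)) {
    d <- identity_desaccaded(tr, eye_filtered = -g * tr$head_vel)
    expect_equal(auc_gain(d)$g_pos, g, tolerance = 1e-10 * max(g, 1))
    expect_equal(auc_gain(d)$g_neg, g, tolerance = 1e-10 * max(g, 1))
    expect_equal(scp_gain(d)$g_pos, g, tolerance = 1e-10 * max(g, 1))
    expect_equal(scp_gain(d)$g_neg, g, tolerance = 1e-10 * max(g, 1))
  }
})

test_that("directional asymmetry of unilateral hypofunction is recovered", {
  gp <- c(); gn <- c()
  for (s in 1:10) {
    sim <- simulate_vvor(vvor_preset("unilateral", seed = s))
    g <- auc_gain(desaccade(select_window(sim$trace)))
    gp <- c(gp, g$g_pos); gn <- c(gn, g$g_neg)
  }
  expect_equal(mean(gp), 0.85, tolerance = 0.05)
  expect_equal(mean(gn), 0.69, tolerance = 0.05)
})
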