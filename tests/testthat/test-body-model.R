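test_that("single-segment CM is the marker midpoint relative to the ankle", {
  s <- one_segment_subject()
  frames <- make_frames(
    time = c(0, 1 / 120),
    positions = list(
      p1 = rbind(c(0, 0, 0), c(0, 0, 0)),
      d1 = rbind(c(1, 0, 1), c(1, 0, 1)),
      ankle_l = rbind(c(0, 0.1, 0), c(0, 0.1, 0)),
      ankle_r = rbind(c(0, -0.1, 0), c(0, -0.1, 0))))
  cm <- estimate_cm(frames, s)
  expect_equal(cm$u, c(0.5, 0.5))
  expect_equal(cm$h, c(0.5, 0.5))
})

test_that("two equal-fraction segments average symmetrically", {
  s <- subject_model(
    70, 1.75,
    segment_table = data.frame(
      segment = c("a", "b"), fraction = c(0.5, 0.5), fraction_sd = c(0, 0),
      proximal = c("a1", "b1"), distal = c("a2", "b2"),
      stringsAsFactors = FALSE))
  frames <- make_frames(
    time = 0,
    positions = list(
      a1 = rbind(c(0, 0, 0)), a2 = rbind(c(0, 0, 0)),   # seg CM (0, 0)
      b1 = rbind(c(1, 0, 1)), b2 = rbind(c(1, 0, 1)),   # seg CM (1, 1)
      ankle_l = rbind(c(0, 0.1, 0)), ankle_r = rbind(c(0, -0.1, 0))))
  cm <- estimate_cm(frames, s)
  expect_equal(c(cm$u, cm$h), c(0.5, 0.5))
})

test_that("CM estimation is linear: doubling marker coordinates doubles it", {
  s <- fx_subject()
  tr <- fixture("trial_noiseless", function()
    make_marker_trial(fx_subject(), fx_profile_var(), noise_sd = 0,
                      seed = 1))
  frames <- tr$frames
  frames2 <- frames
  frames2[, -1] <- 2 * frames2[, -1]
  cm <- estimate_cm(frames, s)
  cm2 <- estimate_cm(frames2, s)
  expect_equal(cm2$u, 2 * cm$u, tolerance = 1e-12)
  expect_equal(cm2$h, 2 * cm$h, tolerance = 1e-12)
})

test_that("frames with missing markers are excluded, many gaps are an error", {
  s <- one_segment_subject()
  n <- 30
  pos <- list(
    p1 = cbind(0, 0, 0)[rep(1, n), ],
    d1 = cbind(1, 0, 1)[rep(1, n), ],
    ankle_l = cbind(0, 0.1, 0)[rep(1, n), ],
    ankle_r = cbind(0, -0.1, 0)[rep(1, n), ])
  frames <- make_frames(seq_len(n) / 120, pos)
  frames$p1_x[3] <- NA
  expect_message(cm <- estimate_cm(frames, s), "excluding 1")
  expect_equal(nrow(cm), n - 1)
  expect_equal(attr(cm, "gaps"), 3L)
  frames$p1_x[1:10] <- NA
  expect_error(estimate_cm(frames, s), "20%")
})

test_that("polar conversion round-trips and handles the axis points", {
  # axis examples
  cm <- data.frame(time = c(0, 1, 2) / 120,
                   u = c(1, 0, 1), h = c(0, 0.9, 0.0001))
  pol <- kinematics_to_polar(cm, cutoff_hz = NULL)
  expect_equal(pol$theta[1], 0)
  expect_equal(pol$l[1], 1)
  expect_equal(pol$theta[2], pi / 2)
  expect_equal(pol$l[2], 0.9)
  # round-trip on a realistic series
  tr <- fixture("trial_noiseless", function()
    make_marker_trial(fx_subject(), fx_profile_var(), noise_sd = 0,
                      seed = 1))
  cm <- tr$cm_true
  pol <- kinematics_to_polar(cm, cutoff_hz = NULL)
  expect_equal(pol$l * cos(pol$theta), cm$u, tolerance = 1e-12)
  expect_equal(pol$l * sin(pol$theta), cm$h, tolerance = 1e-12)
})

test_that("angular velocity recovers an analytic motion at 120 Hz", {
  t <- seq(0, 2, by = 1 / 120)
  theta <- pi / 2 + 0.1 * sin(t)
  cm <- data.frame(time = t, u = 0.9 * cos(theta), h = 0.9 * sin(theta))
  pol <- kinematics_to_polar(cm, cutoff_hz = NULL)
  inner <- 2:(length(t) - 1)
  expect_lt(max(abs(pol$omega[inner] - 0.1 * cos(t[inner]))), 1e-3)
  # smoothing leaves a band-limited signal essentially unchanged away from
  # the series edges
  pol_s <- kinematics_to_polar(cm, cutoff_hz = 6)
  mid <- 60:(length(t) - 60)
  expect_lt(max(abs(pol_s$omega[mid] - 0.1 * cos(t[mid]))), 5e-3)
})

test_that("degenerate CM at the ankle is an error", {
  cm <- data.frame(time = c(0, 1, 2), u = c(1, 0, 1), h = c(0, 0, 0))
  expect_error(kinematics_to_polar(cm), "degenerate")
})

test_that("CM position uncertainty propagates mass-fraction SDs", {
  # all SDs zero -> zero
  s0 <- one_segment_subject(sd = 0)
  frames <- make_frames(
    time = 0,
    positions = list(p1 = rbind(c(0.2, 0, 0.6)), d1 = rbind(c(0.4, 0, 1.2)),
                     ankle_l = rbind(c(0, 0.1, 0)),
                     ankle_r = rbind(c(0, -0.1, 0))))
  expect_equal(cm_position_error(s0, frames), 0)
  # fixed override wins
  expect_equal(cm_position_error(s0, frames, override = 0.015), 0.015)
})

test_that("error propagation matches a Monte-Carlo oracle", {
  # two segments with distinct horizontal offsets
  s <- subject_model(
    70, 1.75,
    segment_table = data.frame(
      segment = c("a", "b"), fraction = c(0.6, 0.4),
      fraction_sd = c(0.03, 0.02),
      proximal = c("a1", "b1"), distal = c("a2", "b2"),
      stringsAsFactors = FALSE))
  ua <- 0.10; ub <- -0.35
  frames <- make_frames(
    time = 0,
    positions = list(
      a1 = rbind(c(ua, 0, 0.5)), a2 = rbind(c(ua, 0, 0.9)),
      b1 = rbind(c(ub, 0, 0.3)), b2 = rbind(c(ub, 0, 0.7)),
      ankle_l = rbind(c(0, 0.1, 0)), ankle_r = rbind(c(0, -0.1, 0))))
  dx <- cm_position_error(s, frames)
  mc <- with_seed(7, {
    f <- cbind(rnorm(1e5, 0.6, 0.03), rnorm(1e5, 0.4, 0.02))
    f <- f / rowSums(f)
    sd(f[, 1] * ua + f[, 2] * ub)
  })
  expect_lt(abs(dx - mc) / mc, 0.05)
})
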