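# Feature extraction is exercised on constructed traces whose features
# are known exactly.

synth_trace <- function(time, values) {
  out <- data.frame(time_s = time, rtotal_au = values)
  class(out) <- c("spindle_trace", "data.frame")
  out
}

test_that("initial burst is the first interior peak above baseline", {
  t <- seq(0, 3, by = 1e-3)

  flat <- synth_trace(t, rep(2, length(t)))
  b <- initial_burst(flat, onset = 1, ramp_end = 1.5)
  expect_equal(b$value, 0)
  expect_false(b$burst_present)

  # baseline 2.0 before onset, peak 3.5 early in the ramp, later apex 5
  x <- rep(2, length(t))
  x[t > 1] <- 2 + 1.5 * exp(-((t[t > 1] - 1.05) / 0.02)^2)
  x[t > 1.2 & t <= 1.5] <- x[t > 1.2 & t <= 1.5] +
    3 * (t[t > 1.2 & t <= 1.5] - 1.2)
  b2 <- initial_burst(synth_trace(t, x), onset = 1, ramp_end = 1.5)
  expect_equal(b2$value, 1.5, tolerance = 1e-3)
  expect_true(b2$burst_present)
  expect_equal(b2$peak_time, 1.05, tolerance = 0.01)
  expect_equal(b2$baseline, 2)

  # a monotone rise peaking only at the apex is not a burst
  mono <- rep(2, length(t)); mono[t > 1] <- 2 + (t[t > 1] - 1)
  b3 <- initial_burst(synth_trace(t, mono), onset = 1, ramp_end = 1.5)
  expect_false(b3$burst_present)

  # presence is referenced to epsilon_frac of a reference burst
  b4 <- initial_burst(synth_trace(t, x), onset = 1, ramp_end = 1.5,
                      reference = 100, epsilon_frac = 0.02)
  expect_false(b4$burst_present) # 1.5 < 2% of 100
  expect_error(initial_burst(flat, onset = 10, ramp_end = 11), "outside")
})

test_that("dynamic response fits a line from the post-burst minimum", {
  t <- seq(0, 3, by = 1e-3)

  # pure line of slope 4 over a 0.5 s ramp, no burst: rise = 4 * 0.5
  lin <- rep(1, length(t)); lin[t > 1] <- 1 + 4 * (t[t > 1] - 1)
  dr <- dynamic_response(synth_trace(t, lin), c(1, 1.5))
  expect_equal(dr$rise, 2, tolerance = 1e-6)
  expect_equal(dr$slope, 4, tolerance = 1e-6)

  const <- synth_trace(t, rep(5, length(t)))
  expect_equal(dynamic_response(const, c(1, 1.5))$rise, 0)

  # burst then dip then line: the fit starts at the dip
  x <- rep(1, length(t))
  x[t > 1] <- 1 + 2 * exp(-((t[t > 1] - 1.03) / 0.015)^2)
  x[t > 1.1] <- x[t > 1.1] + 3 * (t[t > 1.1] - 1.1)
  dr2 <- dynamic_response(synth_trace(t, x), c(1, 1.5))
  expect_gt(dr2$fit_start, 1.05)
  expect_equal(dr2$slope, 3, tolerance = 0.1)

  # adding a constant leaves slope and rise unchanged
  dr3 <- dynamic_response(synth_trace(t, x + 42), c(1, 1.5))
  expect_equal(dr3$rise, dr2$rise, tolerance = 1e-9)
})

test_that("dynamic index is the late-ramp peak minus the hold value", {
  t <- seq(0, 3, by = 1e-3)
  x <- rep(0.5, length(t))
  x[t > 1 & t <= 1.5] <- 0.5 + 3 * (t[t > 1 & t <= 1.5] - 1) # peak 2.0
  x[t > 1.5] <- 0.5 # hold at 0.5
  di <- dynamic_index(synth_trace(t, x), c(1, 1.5), hold_end = 3)
  expect_equal(di, 1.5, tolerance = 1e-2)
  expect_equal(dynamic_index(synth_trace(t, rep(1, length(t))),
                             c(1, 1.5), 3), 0)
  # shift-invariant
  di2 <- dynamic_index(synth_trace(t, x + 7), c(1, 1.5), hold_end = 3)
  expect_equal(di2, di)
})

test_that("recovery time finds the threshold crossing after the test onset", {
  t <- seq(0, 5, by = 1e-3)
  base <- 1
  x <- rep(base, length(t))
  x[t > 1 & t <= 2] <- 6              # conditioning peak 6
  x[t > 2 & t <= 3.1] <- -2           # collapsed
  x[t > 3.1] <- 6                      # reappears 0.1 s after onset at 3
  rt <- recovery_time(synth_trace(t, x), second_onset = 3, cond_onset = 1)
  expect_equal(rt, 0.1, tolerance = 0.02) # sampling-grid slack

  # already above threshold at onset
  z <- rep(1, length(t)); z[t > 1.5] <- 8
  rt0 <- recovery_time(synth_trace(t, z), second_onset = 3,
                       cond_onset = 1)
  expect_equal(rt0, 0)

  # never recovers
  y <- x; y[t > 2] <- -2
  expect_true(is.na(recovery_time(synth_trace(t, y), 3, 1)))
  expect_error(recovery_time(synth_trace(t, x), 99, 1), "outside")
})

test_that("extract_features reads the stretch timing from the protocol", {
  tr <- simulate_spindle(ramp_hold(36, 5.6), dt = 2e-4)
  fs <- extract_features(tr)
  expect_named(fs, c("initial_burst", "burst_present", "dynamic_response",
                     "dynamic_slope", "dynamic_index"))
  expect_true(fs$burst_present)
  expect_gt(fs$initial_burst, 0)
  expect_gt(fs$dynamic_index, 0)
  expect_error(extract_features(data.frame(time_s = 1, rtotal_au = 1)),
               "protocol events")
})
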