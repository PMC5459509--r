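test_that("resting potential is the baseline median", {
  flat <- voltage_trace((0:4999) / 2000, rep(-40, 5000), 2000)
  expect_equal(resting_potential(flat), -40)
  spc <- synth_spec("wt_young", duration_s = 20, seed = 1,
                    rest_vm_mv = -42, noise_sd = 1)
  vt <- render_voltage_trace(make_beat_schedule(spc), spc)
  expect_lt(abs(resting_potential(vt) - (-42)), 0.5)
  # a trace that is all event, no baseline, errors
  t <- (0:4999) / 2000
  v <- -40 + 50 * abs(sin(2 * pi * t))  # never settles near the minimum
  expect_error(resting_potential(voltage_trace(t, v, 2000)),
               "baseline")
})

test_that("wt resting estimates stay in the physiological -50..-35 mV", {
  rests <- vapply(1:6, function(s) {
    spc <- synth_spec("wt_young", duration_s = 20, seed = s)
    resting_potential(render_voltage_trace(make_beat_schedule(spc), spc))
  }, 0)
  expect_true(all(rests > -50 & rests < -35))
})

test_that("the analytic linear AP yields APD10/50/90 = 10/50/90 ms", {
  for (rate in c(2000, 5000)) {
    vt <- linear_ap_trace(rate = rate)
    ev <- detect_events(vt, smooth_ms = 0)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$class, "single")
    tol <- 1000 / rate  # one sample, in ms
    expect_equal(ev$apd10, 10, tolerance = tol)
    expect_equal(ev$apd50, 50, tolerance = tol)
    expect_equal(ev$apd90, 90, tolerance = tol)
    expect_true(ev$apd10 <= ev$apd50 && ev$apd50 <= ev$apd90)
    expect_equal(attr(ev, "resting_vm"), -40, tolerance = 0.01)
    expect_equal(ev$max_amplitude, 50, tolerance = 0.1)
  }
})

test_that("exponential repolarization crosses APD50 at tau ln 2", {
  rate <- 5000; tau <- 0.030
  t <- seq(0, 3, by = 1 / rate)
  t_up <- 1.5
  v <- ifelse(t < t_up, -40, -40 + 50 * exp(-(t - t_up) / tau))
  vt <- voltage_trace(t, v, rate)
  ev <- detect_events(vt, smooth_ms = 0)
  expect_equal(nrow(ev), 1L)
  # expected: (peak - onset) upstroke offset + tau ln 2 from the peak
  offset_ms <- (t_up - ev$onset) * 1000
  expect_equal(ev$apd50, offset_ms + tau * log(2) * 1000,
               tolerance = 1000 / rate)
  expect_equal(ev$apd90, offset_ms + tau * log(10) * 1000,
               tolerance = 1000 / rate)
})

test_that("flat traces yield empty tables; programmed singles count", {
  flat <- voltage_trace((0:9999) / 2000, rep(-40, 10000), 2000)
  ev <- detect_events(flat)
  expect_equal(nrow(ev), 0L)
  spc <- synth_spec("wt_young", duration_s = 30, seed = 2, noise_sd = 0,
                    ead_prob = 0, burst_prob = 0)
  gt <- make_beat_schedule(spc)
  ev <- detect_events(render_voltage_trace(gt, spc))
  expect_equal(nrow(ev), nrow(gt$ap_events))
  expect_true(all(ev$n_peaks == 1))
  expect_true(all(ev$class == "single"))
})

test_that("burst grouping keeps an 8-peak burst as one event", {
  spc <- synth_spec("kcnq_like", duration_s = 6, seed = 3, noise_sd = 0,
                    burst_prob = 1, peaks_per_burst_dist = c(8, 0),
                    di_dist = c(3, 0), si_dist = c(0.25, 0))
  gt <- make_beat_schedule(spc)
  ev <- detect_events(render_voltage_trace(gt, spc))
  expect_equal(nrow(ev), nrow(gt$ap_events))
  expect_true(all(ev$n_peaks == 8))
  expect_true(all(ev$class == "burst"))
  # event duration matches the analytic schedule value
  expect_equal(ev$event_duration, gt$ap_events$event_duration,
               tolerance = 2)
})

test_that("event features close the loop on the generator with noise", {
  for (preset in c("wt_young", "sei_like", "kcnq_like")) {
    spc <- synth_spec(preset, duration_s = 30, seed = 7)
    gt <- make_beat_schedule(spc)
    ev <- detect_events(render_voltage_trace(gt, spc))
    n_expected <- oracle_grouped_events(gt$ap_events$onset)
    expect_equal(nrow(ev), n_expected)
    if (nrow(ev) == nrow(gt$ap_events)) {
      expect_gt(mean(ev$class == gt$ap_events$class), 0.9)
      expect_equal(mean(ev$n_peaks), mean(gt$ap_events$n_peaks),
                   tolerance = 0.15)
    }
  }
})

test_that("peak totals match a brute-force scan on noise-free traces", {
  spc <- synth_spec("sei_like", duration_s = 20, seed = 4, noise_sd = 0)
  gt <- make_beat_schedule(spc)
  vt <- render_voltage_trace(gt, spc)
  ev <- detect_events(vt, smooth_ms = 0)
  expect_equal(sum(ev$n_peaks),
               oracle_peak_count(vt$v, spc$rest_vm_mv + 10))
})

test_that("classification follows the stated peak-count/morphology rules", {
  expect_equal(classify_event(1, 0.0, 50), "single")
  expect_equal(classify_event(2, c(0, 0.07), c(50, 28)), "ead_double")
  expect_equal(classify_event(2, c(0, 0.07), c(50, 49)), "burst")
  expect_equal(classify_event(2, c(0, 0.40), c(50, 28)), "burst")
  expect_equal(classify_event(8, seq(0, 0.84, by = 0.12), rep(50, 8)),
               "burst")
  # generator EADs come back labeled as such (noise-free)
  spc <- synth_spec("sei_like", duration_s = 30, seed = 5, noise_sd = 0,
                    ead_prob = 1, burst_prob = 0)
  gt <- make_beat_schedule(spc)
  ev <- detect_events(render_voltage_trace(gt, spc))
  expect_true(all(ev$class == "ead_double"))
  expect_true(all(ev$n_peaks == 2))
  expect_true(all(is.na(ev$apd50)))  # APDs absent for multi-peak events
})

test_that("classification is invariant to a constant voltage offset", {
  spc <- synth_spec("sei_like", duration_s = 20, seed = 6)
  vt <- render_voltage_trace(make_beat_schedule(spc), spc)
  ev1 <- detect_events(vt)
  vt2 <- vt; vt2$v <- vt$v + 17.3
  ev2 <- detect_events(vt2)
  expect_equal(ev1$class, ev2$class)
  expect_equal(ev1$n_peaks, ev2$n_peaks)
  expect_equal(ev1$max_amplitude, ev2$max_amplitude, tolerance = 1e-6)
})

test_that("record summary averages and warns as specified", {
  spc <- synth_spec("wt_young", duration_s = 30, seed = 8, noise_sd = 0,
                    ead_prob = 0, burst_prob = 0)
  ev <- detect_events(render_voltage_trace(make_beat_schedule(spc), spc))
  s <- record_summary(ev, duration_s = 30)  # ~32 singles: no warning
  expect_equal(s$mean_peaks_per_burst, 1)
  expect_equal(s$apd50, mean(ev$apd50), tolerance = 1e-9)
  expect_false(s$apd_below_minimum)
  # below the 20-AP convention: mean still emitted, with a warning
  expect_warning(s10 <- record_summary(ev[1:10, ], duration_s = 30),
                 "single APs")
  expect_true(is.finite(s10$apd50))
  # cohort ordering: kcnq-like flies above wt-like in peaks/burst
  mean_ppb <- function(preset, s0) {
    mean(vapply(1:3, function(h) {
      spc <- synth_spec(preset, duration_s = 30, seed = s0 + h)
      ev <- detect_events(render_voltage_trace(make_beat_schedule(spc), spc))
      suppressWarnings(record_summary(ev, 30)$mean_peaks_per_burst)
    }, 0))
  }
  expect_gt(mean_ppb("kcnq_like", 40), mean_ppb("wt_young", 40))
  expect_warning(record_summary(ev, duration_s = 10), "shorter")
})
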