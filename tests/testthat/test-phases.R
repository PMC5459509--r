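test_that("movement trace differentiates correctly", {
  flat <- diameter_trace((0:499) / 200, rep(70, 500), 200)
  expect_true(all(movement_trace(flat)$s == 0))
  # linear ramp 80 -> 60 um over 0.1 s: interior speed 200 um/s
  t <- (0:199) / 200
  d <- approx(c(0, 0.4, 0.5, 1), c(80, 80, 60, 60), xout = t)$y
  sp <- movement_trace(diameter_trace(t, d, 200))
  interior <- t > 0.42 & t < 0.48
  expect_equal(sp$s[interior], rep(200, sum(interior)), tolerance = 1e-9)
})

test_that("triangular beats give two speed peaks per beat", {
  spc <- synth_spec("wt_young", duration_s = 10, seed = 2, noise_sd = 0,
                    iso_s = 0.03)
  gt <- make_beat_schedule(spc)
  sp <- movement_trace(render_diameter_trace(gt, spc))
  thr <- 0.5 * max(sp$s)
  n_episodes <- sum(diff(c(FALSE, sp$s > thr)) == 1)
  expect_equal(n_episodes, 2L * nrow(gt$beats))
})

test_that("noise-free phases match ground truth within one sample", {
  spc <- synth_spec("wt_young", duration_s = 30, seed = 1, noise_sd = 0)
  gt <- make_beat_schedule(spc)
  tr <- render_diameter_trace(gt, spc)
  bt <- segment_beats(tr)
  ph <- parse_phases(movement_trace(tr), bt)
  g <- gt$beats
  tol <- 1 / spc$fps + 1e-9
  expect_true(all(abs(ph$sp - g$sp) <= tol))
  expect_true(all(abs(ph$iso - g$iso) <= tol))
  expect_true(all(abs(ph$lp - g$lp) <= tol))
  expect_false(any(ph$flagged))
  v_true <- (g$dd - g$sd) / g$sp
  expect_lt(median(abs(ph$shortening_velocity - v_true) / v_true), 0.05)
})

test_that("parse_phases equals the exhaustive threshold-crossing oracle", {
  for (preset in c("wt_young", "sei_like", "load")) {
    spc <- synth_spec(preset, duration_s = 20, seed = 3, noise_sd = 0)
    gt <- make_beat_schedule(spc)
    tr <- render_diameter_trace(gt, spc)
    bt <- segment_beats(tr)
    sp <- movement_trace(tr)
    ph <- parse_phases(sp, bt, threshold = 0.15)
    for (k in seq_len(nrow(bt))) {
      idx <- which(sp$t >= bt$onset[k] & sp$t < bt$relaxation_end[k])
      s <- sp$s[idx]
      orc <- oracle_phases(s, 1 / spc$fps, 0.15 * max(s))
      expect_equal(unname(c(ph$sp[k], ph$iso[k], ph$lp[k])), unname(orc),
                   tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold shrinks SP/LP and grows ISO", {
  spc <- synth_spec("wt_young", duration_s = 12, seed = 4, noise_sd = 0)
  tr <- render_diameter_trace(make_beat_schedule(spc), spc)
  bt <- segment_beats(tr)
  sp <- movement_trace(tr)
  prev <- NULL
  for (thr in c(0.15, 0.3, 0.45)) {
    ph <- parse_phases(sp, bt, threshold = thr)
    if (!is.null(prev)) {
      ok <- !ph$flagged & !prev$flagged
      expect_true(all(ph$sp[ok] <= prev$sp[ok] + 1e-12))
      expect_true(all(ph$lp[ok] <= prev$lp[ok] + 1e-12))
      expect_true(all(ph$iso[ok] >= prev$iso[ok] - 1e-12))
    }
    prev <- ph
  }
})

test_that("phase durations are invariant to a constant diameter offset", {
  spc <- synth_spec("wt_young", duration_s = 12, seed = 5, noise_sd = 0)
  tr <- render_diameter_trace(make_beat_schedule(spc), spc)
  bt <- segment_beats(tr)
  ph1 <- parse_phases(movement_trace(tr), bt)
  tr2 <- tr; tr2$d <- tr$d + 13.7
  ph2 <- parse_phases(movement_trace(tr2), bt)
  expect_equal(ph1$sp, ph2$sp)
  expect_equal(ph1$iso, ph2$iso)
  expect_equal(ph1$lp, ph2$lp)
})

test_that("threshold above peak speed flags the beat", {
  spc <- synth_spec("wt_young", duration_s = 8, seed = 6, noise_sd = 0)
  tr <- render_diameter_trace(make_beat_schedule(spc), spc)
  bt <- segment_beats(tr)
  ph <- parse_phases(movement_trace(tr), bt, threshold = 1e5,
                     type = "absolute")
  expect_true(all(ph$flagged))
  expect_true(all(is.na(ph$iso)))
  expect_error(parse_phases(movement_trace(tr), bt, threshold = -1),
               "threshold")
})

test_that("shortening velocity implements the stated closed form", {
  expect_equal(shortening_velocity(80, 60, 0.1), 200)
  expect_equal(shortening_velocity(75, 75, 0.1), 0)
  expect_error(shortening_velocity(80, 60, 0), "SP")
  expect_error(shortening_velocity(60, 80, 0.1), "DD")
})

test_that("load protocol report recovers programmed ISO response", {
  sim <- function(preset, n, seed0) {
    out <- list()
    for (h in seq_len(n)) {
      spc <- synth_spec(preset, duration_s = 15, seed = seed0 + h)
      tr <- render_diameter_trace(make_beat_schedule(spc), spc)
      bt <- segment_beats(tr)
      out[[sprintf("h%02d", h)]] <-
        parse_phases(movement_trace(tr, 5), bt)
    }
    out
  }
  pre <- sim("wt_young", 6, 300)
  load <- sim("load", 6, 400)
  post <- sim("wt_young", 6, 500)
  rep <- load_protocol_report(pre, load, post)
  expect_gt(rep$summary$mean_delta_iso_load, 0.015)  # programmed 2x ISO
  expect_gt(rep$summary$recovery_fraction, 0.5)
  # identical tables: all contrasts zero, full recovery
  rep0 <- load_protocol_report(pre, pre, pre)
  expect_equal(rep0$summary$mean_delta_iso_load, 0)
  expect_equal(rep0$summary$recovery_fraction, 1)
  expect_error(load_protocol_report(pre, load[-1], post), "missing")
})
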