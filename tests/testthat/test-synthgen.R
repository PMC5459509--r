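test_that("spec validation enforces the declared invariants", {
  expect_s3_class(synth_spec("wt_young"), "synth_spec")
  expect_error(synth_spec("wt_young", sd_um = 90), "sd_um")
  expect_error(synth_spec("wt_young", ead_prob = 1.5), "ead_prob")
  expect_error(synth_spec("wt_young", duration_s = -1), "duration_s")
  expect_error(synth_spec("wt_young", sp_s = 0.2, iso_s = 0.2, lp_s = 0.2),
               "exceed")
  expect_error(synth_spec("wt_young", amp_mv = -5), "amp_mv")
})

test_that("wt_young schedule draws DIs in the expected 0.5-0.8 s range", {
  gt <- make_beat_schedule(synth_spec("wt_young", seed = 1))
  dis <- gt$beats$di[is.finite(gt$beats$di)]
  expect_true(all(dis > 0.5 & dis < 0.8))
  sis <- gt$beats$si
  expect_true(all(sis > 0.2 & sis < 0.28 + 0.05))
})

test_that("zero-variance schedule packs exactly the analytic beat count", {
  sp <- synth_spec("wt_young", duration_s = 8.5,
                   di_dist = c(0.6, 0), si_dist = c(0.25, 0))
  gt <- make_beat_schedule(sp)
  expect_equal(nrow(gt$beats), 10L)
  hp <- diff(gt$beats$onset)
  expect_equal(hp, rep(0.85, 9), tolerance = 1e-12)
})

test_that("schedule errors when the record cannot hold one beat", {
  expect_error(make_beat_schedule(synth_spec("wt_young", duration_s = 0.3)),
               "too short")
})

test_that("sei-like schedules are more irregular than wt at the same seed", {
  for (s in c(1, 5, 9)) {
    gw <- make_beat_schedule(synth_spec("wt_young", seed = s))
    gs <- make_beat_schedule(synth_spec("sei_like", seed = s))
    rel_var <- function(g) {
      hp <- diff(g$beats$onset)
      sd(hp) / median(hp)
    }
    expect_gt(rel_var(gs), rel_var(gw))
  }
})

test_that("generation is deterministic and draws respect truncation", {
  sp <- synth_spec("sei_like", seed = 42)
  g1 <- make_beat_schedule(sp)
  g2 <- make_beat_schedule(sp)
  expect_identical(g1, g2)
  t1 <- render_diameter_trace(g1, sp)
  t2 <- render_diameter_trace(g2, sp)
  expect_identical(t1$d, t2$d)
  expect_true(all(g1$beats$di >= 2 / sp$fps - 1e-12, na.rm = TRUE))
  expect_true(all(g1$beats$si >= 2 / sp$fps - 1e-12))
})

test_that("noise-free diameter trace hits the declared extrema exactly", {
  sp <- synth_spec("wt_young", duration_s = 10, seed = 2, noise_sd = 0)
  tr <- render_diameter_trace(make_beat_schedule(sp), sp)
  expect_equal(min(tr$d), sp$sd_um)
  expect_equal(max(tr$d), sp$dd_um)
  expect_length(tr$d, 10 * sp$fps)
})

test_that("beat count is conserved in the noise-free rendered trace", {
  for (preset in c("wt_young", "sei_like")) {
    sp <- synth_spec(preset, duration_s = 20, seed = 3, noise_sd = 0)
    gt <- make_beat_schedule(sp)
    tr <- render_diameter_trace(gt, sp)
    # count contraction episodes directly: excursions below DD - 1 um
    below <- tr$d < sp$dd_um - 1
    episodes <- sum(diff(c(FALSE, below)) == 1)
    expect_equal(episodes, nrow(gt$beats))
  }
})

test_that("load preset doubles the isometric hold near systolic diameter", {
  # zero-variance schedules: time per beat within 1 um of the systolic
  # diameter is analytic: ISO + the 1-um tails of both linear ramps
  t_bottom <- function(sp) {
    gt <- make_beat_schedule(sp)
    tr <- render_diameter_trace(gt, sp)
    sum(tr$d <= sp$sd_um + 1) / sp$fps / nrow(gt$beats)
  }
  base <- synth_spec("wt_young", duration_s = 20, seed = 4, noise_sd = 0,
                     di_dist = c(0.65, 0), si_dist = c(0.25, 0))
  load <- synth_spec("load", duration_s = 20, seed = 4, noise_sd = 0,
                     di_dist = c(0.65, 0), si_dist = c(0.28, 0))
  tails <- (base$sp_s + base$lp_s) * 1 / (base$dd_um - base$sd_um)
  expect_lt(abs(t_bottom(base) - (base$iso_s + tails)), 2 / base$fps)
  expect_lt(abs(t_bottom(load) - (load$iso_s + tails)), 2 / load$fps)
  # the isometric component itself doubles (0.03 s -> 0.06 s)
  expect_equal((t_bottom(load) - tails) / (t_bottom(base) - tails), 2,
               tolerance = 0.15)
})

test_that("single-beat shortening segment spans duration x fps samples", {
  sp <- synth_spec("wt_young", duration_s = 3, fps = 200, noise_sd = 0,
                   di_dist = c(1, 0), si_dist = c(0.25, 0), seed = 1)
  gt <- make_beat_schedule(sp)
  tr <- render_diameter_trace(gt, sp)
  b <- gt$beats[1, ]
  in_ramp <- tr$t > b$onset & tr$t < b$onset + b$sp
  expect_equal(sum(in_ramp), round(b$sp * sp$fps), tolerance = 1)
})

test_that("voltage rendering respects rest/amplitude bounds", {
  sp <- synth_spec("wt_young", duration_s = 10, seed = 5, noise_sd = 0)
  gt <- make_beat_schedule(sp)
  vt <- render_voltage_trace(gt, sp)
  # apex falls between samples; one sample lies within amp * dt / upstroke
  expect_lt(abs(max(vt$v) - (sp$rest_vm_mv + sp$amp_mv)),
            sp$amp_mv / (sp$ephys_rate * sp$upstroke_s))
  expect_equal(min(vt$v), sp$rest_vm_mv)
  expect_error(render_voltage_trace(gt, synth_spec("wt_young", ephys_rate = 500)),
               "2 kHz")
})

test_that("burst events render the programmed number of local maxima", {
  sp <- synth_spec("kcnq_like", duration_s = 12, seed = 6, noise_sd = 0,
                   burst_prob = 1, peaks_per_burst_dist = c(8, 0),
                   di_dist = c(1.6, 0), si_dist = c(0.25, 0))
  gt <- make_beat_schedule(sp)
  expect_true(all(gt$ap_events$n_peaks == 8))
  vt <- render_voltage_trace(gt, sp)
  floor_v <- sp$rest_vm_mv + 10
  total_peaks <- oracle_peak_count(vt$v, floor_v)
  expect_equal(total_peaks, sum(gt$ap_events$n_peaks))
})

test_that("kcnq-like preset programs more peaks/event than sei-like", {
  for (s in c(3, 8)) {
    gk <- make_beat_schedule(synth_spec("kcnq_like", seed = s))
    gs <- make_beat_schedule(synth_spec("sei_like", seed = s))
    expect_gt(mean(gk$ap_events$n_peaks), mean(gs$ap_events$n_peaks))
  }
})

test_that("sync pair raises TTL exactly over the movie window", {
  sp <- synth_spec("wt_young", duration_s = 6, seed = 7)
  gt <- make_beat_schedule(sp)
  pair <- render_sync_pair(gt, sp, pad_s = 2)
  aux <- pair$voltage$aux
  t <- pair$voltage$t
  on <- aux > max(aux) / 2
  expect_true(all(t[on] >= 2 - 1e-9 & t[on] < 8))
  expect_true(all(!on[t < 2 | t >= 8]))
  expect_equal(pair$window, c(2, 8))
})

test_that("rendered values stay inside declared ranges given the noise", {
  sp <- synth_spec("wt_young", duration_s = 10, seed = 8)  # noise_sd = 1
  gt <- make_beat_schedule(sp)
  tr <- render_diameter_trace(gt, sp)
  expect_true(all(tr$d > sp$sd_um - 6 & tr$d < sp$dd_um + 6))
  vt <- render_voltage_trace(gt, sp)
  expect_true(all(vt$v < sp$rest_vm_mv + sp$amp_mv + 6))
})
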