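test_that("noise-free intervals are recovered within one frame period", {
  sp <- synth_spec("wt_young", duration_s = 30, seed = 1, noise_sd = 0,
                   di_dist = c(0.60, 0), si_dist = c(0.25, 0))
  gt <- make_beat_schedule(sp)
  bt <- segment_beats(render_diameter_trace(gt, sp))
  expect_equal(nrow(bt), nrow(gt$beats))
  g <- gt$beats
  tol <- 1 / sp$fps
  expect_true(all(abs(bt$si - g$si) < tol))
  expect_true(all(abs(bt$di - g$di) < tol, na.rm = TRUE))
  expect_true(all(abs(bt$hp - (g$si + g$di)) < tol, na.rm = TRUE))
  expect_equal(bt$dd, g$dd, tolerance = 1e-9)
  expect_equal(bt$sd, g$sd, tolerance = 1e-9)
})

test_that("constant and too-short traces are handled explicitly", {
  flat <- diameter_trace((0:999) / 200, rep(80, 1000), 200)
  expect_warning(bt <- segment_beats(flat), "no beats")
  expect_equal(nrow(bt), 0L)
  expect_error(segment_beats(diameter_trace((0:99) / 200, rep(80, 100), 200)),
               "2 s")
  tt <- c((0:500) / 200, 3 + (0:500) / 200)
  expect_error(segment_beats(diameter_trace(tt, rep(80, length(tt)), 200)),
               "uniform")
})

test_that("wt_young mean SIs across seeds land in the 0.2-0.28 s range", {
  msi <- vapply(1:10, function(s) {
    sp <- synth_spec("wt_young", duration_s = 30, seed = s)
    bt <- segment_beats(render_diameter_trace(make_beat_schedule(sp), sp))
    mean(bt$si)
  }, 0)
  expect_true(all(msi > 0.2 & msi < 0.28))
})

test_that("summary reproduces the stated AI and FS arithmetic", {
  bt <- make_beat_table(onsets = c(0, 0.8, 1.8, 3.0),
                        sis = rep(0.25, 4), dd = 80, sd = 60)
  s <- summarize_beats(bt)
  expect_equal(s$ai, 0.2)                      # sd {0.8,1,1.2} / median 1
  expect_equal(s$ai, oracle_ai(bt$hp[1:3]))
  expect_equal(s$fs, 0.25)
  bt2 <- make_beat_table(onsets = c(0, 1, 2, 3), sis = rep(0.25, 4))
  expect_equal(summarize_beats(bt2)$ai, 0)
})

test_that("AI matches the brute-force oracle on arbitrary tables", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    onsets <- cumsum(c(0, runif(n - 1, 0.3, 2)))
    bt <- make_beat_table(onsets, sis = runif(n, 0.1, 0.3))
    expect_equal(summarize_beats(bt)$ai, oracle_ai(bt$hp[1:(n - 1)]),
                 tolerance = 1e-12)
  }
})

test_that("AI is absent (not zero) below three beats", {
  bt <- make_beat_table(c(0, 1), sis = c(0.25, 0.25))
  expect_true(is.na(summarize_beats(bt)$ai))
})

test_that("FS is invariant to um-per-pixel rescaling", {
  sp <- synth_spec("wt_young", duration_s = 20, seed = 6)
  tr <- render_diameter_trace(make_beat_schedule(sp), sp)
  fs1 <- summarize_beats(segment_beats(tr))$fs
  tr2 <- tr; tr2$d <- tr$d * 3.7
  fs2 <- summarize_beats(segment_beats(tr2))$fs
  expect_equal(fs1, fs2, tolerance = 1e-9)
})

test_that("record time is conserved across segmented beats", {
  sp <- synth_spec("wt_young", duration_s = 30, seed = 9, noise_sd = 0)
  bt <- segment_beats(render_diameter_trace(make_beat_schedule(sp), sp))
  n <- nrow(bt)
  total <- sum(bt$si[-n]) + sum(bt$di[-n])
  expect_equal(total, bt$onset[n] - bt$onset[1], tolerance = 1e-9)
})

test_that("DI histogram bins, normalizes and reports totals as stated", {
  bt <- make_beat_table(c(0, 0.8, 1.7, 2.6, 3.6),
                        sis = c(0.25, 0.15, 0.25, 0.25, 0.25))
  # DIs: 0.55, 0.75, 0.65, 0.75
  bt$di[1:4] <- c(0.55, 0.65, 0.65, 0.75)
  h <- di_histogram(bt, bin_width = 0.1)
  expect_equal(h$n_total, 4L)
  lo <- h$bin_edges[-length(h$bin_edges)]
  expect_equal(h$percent[which(abs(lo - 0.5) < 1e-9)], 25)
  expect_equal(h$percent[which(abs(lo - 0.6) < 1e-9)], 50)
  expect_equal(h$percent[which(abs(lo - 0.7) < 1e-9)], 25)
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_error(di_histogram(bt, bin_width = 0), "bin_width")
})

test_that("a +0.1 s DI shift moves the modal bin by exactly one", {
  set.seed(3)
  onsets <- cumsum(c(0, runif(60, 0.8, 1.0)))
  a <- make_beat_table(onsets, sis = rep(0.25, 61))
  b <- a
  b$di <- a$di + 0.1
  ha <- di_histogram(a, 0.1); hb <- di_histogram(b, 0.1)
  expect_equal(which.max(hb$percent), which.max(ha$percent) + 1L)
})

test_that("pre/post comparison recovers programmed drug effects", {
  sim_cohort <- function(di_mean, n_hearts, duration, seed0) {
    out <- list()
    for (h in seq_len(n_hearts)) {
      sp <- synth_spec("wt_young", duration_s = duration,
                       di_dist = c(di_mean, 0.05), seed = seed0 + h)
      out[[sprintf("h%02d", h)]] <-
        segment_beats(render_diameter_trace(make_beat_schedule(sp), sp))
    }
    out
  }
  pre <- sim_cohort(0.60, 8, 30, 100)
  post <- sim_cohort(0.75, 8, 30, 200)   # +0.15 s DI programmed
  rep <- compare_pre_post(pre, post)
  expect_equal(rep$summary$mean_delta_di, 0.15, tolerance = 0.02)
  expect_lt(rep$n_ratio, 1)  # slower rhythm, fewer beats in 30 s
  # identical tables: all deltas zero
  rep0 <- compare_pre_post(pre, pre)
  expect_equal(rep0$summary$mean_delta_di, 0)
  expect_equal(rep0$n_ratio, 1)
  expect_false(rep0$beat_count_reduced)
  # unpaired IDs error names the offender
  expect_error(compare_pre_post(pre, post[-1]), "h01")
})
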