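# Shared fixtures and independent oracles (kept deliberately naive and
# separate from the package implementation paths).

# beat_table builder from explicit onset/SI sequences
make_beat_table <- function(onsets, sis, dd = 80, sd = 60) {
  stopifnot(length(onsets) == length(sis))
  n <- length(onsets)
  bt <- data.frame(onset = onsets, relaxation_end = onsets + sis)
  bt$si <- sis
  bt$di <- c(onsets[-1], NA) - bt$relaxation_end
  bt$hp <- c(diff(onsets), NA)
  bt$dd <- dd
  bt$sd <- sd
  class(bt) <- c("beat_table", "data.frame")
  bt
}

# brute-force arrhythmia index: explicit SD and median over the HP list
oracle_ai <- function(hps) {
  m <- sort(hps)
  med <- if (length(m) %% 2 == 1) m[(length(m) + 1) / 2] else
    (m[length(m) / 2] + m[length(m) / 2 + 1]) / 2
  mu <- sum(hps) / length(hps)
  s <- sqrt(sum((hps - mu)^2) / (length(hps) - 1))
  s / med
}

# brute-force phase segmentation: exhaustive per-sample threshold-crossing
# scan over one beat's speed samples, with the same boundary convention as
# the package (interpolated crossings of max(threshold, half episode
# peak)), written as an explicit independent loop
oracle_phases <- function(s, dt, thr) {
  n <- length(s)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (s[i] >= thr) {
      j <- i
      while (j < n && s[j + 1] >= thr) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) < 2) return(NULL)
  edge <- function(a, b) {
    lvl <- thr
    pk <- -Inf
    for (q in a:b) if (s[q] > pk) pk <- s[q]
    if (0.5 * pk > lvl) lvl <- 0.5 * pk
    a2 <- a; while (s[a2] < lvl) a2 <- a2 + 1
    b2 <- b; while (s[b2] < lvl) b2 <- b2 - 1
    rise <- if (a2 > 1 && s[a2 - 1] < lvl) {
      (a2 - 1 + (lvl - s[a2 - 1]) / (s[a2] - s[a2 - 1]) - 1) * dt
    } else (a2 - 1) * dt
    fall <- if (b2 < n && s[b2 + 1] < lvl) {
      (b2 + (lvl - s[b2]) / (s[b2 + 1] - s[b2]) - 1) * dt
    } else (b2 - 1) * dt
    c(rise, fall)
  }
  f <- runs[[1]]; l <- runs[[length(runs)]]
  ef <- edge(f[1], f[2]); el <- edge(l[1], l[2])
  c(sp = ef[2] - ef[1], iso = el[1] - ef[2], lp = el[2] - el[1])
}

# brute-force peak scan on a noise-free voltage vector: every strict local
# maximum above the floor
oracle_peak_count <- function(v, floor_v) {
  cnt <- 0L
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] >= floor_v) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# expected number of analysis events after the grouping rule, computed
# from ground-truth onsets (events whose onsets are within window merge)
oracle_grouped_events <- function(onsets, window_s = 0.3) {
  sum(c(TRUE, diff(onsets) > window_s))
}

# analytic single AP on a time grid: instantaneous upstroke at t_up,
# linear repolarization over `repol` seconds
linear_ap_trace <- function(rate = 2000, rest = -40, peak = 10,
                            t_up = 1, repol = 0.1, total = 3) {
  t <- seq(0, total, by = 1 / rate)
  v <- ifelse(t < t_up, rest,
              ifelse(t <= t_up + repol,
                     peak - (peak - rest) * (t - t_up) / repol, rest))
  voltage_trace(t, v, rate)
}
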