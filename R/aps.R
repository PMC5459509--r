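# Intracellular action-potential feature extraction: resting potential,
# event detection and burst grouping, amplitudes, event duration,
# APD10/50/90, and event classification (single / EAD double-peak / burst).

#' Resting membrane potential
#'
#' Median of the samples in the baseline band (below a cutoff at
#' `band_frac` of the trace's voltage range above its minimum), i.e. the
#' samples outside depolarized events. A trace with a negligible voltage
#' range (no events) returns the plain median.
#'
#' @param trace A [voltage_trace()].
#' @param band_frac Baseline band cutoff as a fraction of the voltage
#'   range (default 0.25).
#' @param min_baseline_s Minimum required baseline time, seconds
#'   (default 1).
#' @return Resting potential, mV.
#' @export
resting_potential <- function(trace, band_frac = 0.25, min_baseline_s = 1) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$v
  rng <- diff(range(v))
  if (rng < 1) return(stats::median(v))
  base <- v <= min(v) + band_frac * rng
  if (sum(base) / trace$rate < min_baseline_s) {
    stop("no usable inter-event baseline segment (< ",
         min_baseline_s, " s)", call. = FALSE)
  }
  stats::median(v[base])
}

# local maxima (strictly greater than the left neighbor, at least the
# right: tolerates sampled plateau tops) above a height floor, thinned by
# (a) a minimum separation and (b) a minimum dip: a retained peak must be
# separated from its nearest retained neighbors by a trough at least
# `min_dip` below it (prominence, so noise ripple on a slow
# repolarization never counts as extra peaks)
.find_peaks <- function(v, floor_v, min_sep, min_dip = 3) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] >= floor_v]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (length(kept)) {
      if (min(abs(kept - p)) < min_sep) next
      left <- kept[kept < p]; right <- kept[kept > p]
      dip_ok <- TRUE
      if (length(left)) {
        dip_ok <- dip_ok && min(v[max(left):p]) <= v[p] - min_dip
      }
      if (length(right)) {
        dip_ok <- dip_ok && min(v[p:min(right)]) <= v[p] - min_dip
      }
      if (!dip_ok) next
    }
    kept <- c(kept, p)
  }
  sort(kept)
}

# interpolated crossing time of level `lvl` between samples i and i+1
.xing <- function(t, v, i, lvl) {
  t[i] + (lvl - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Detect and group electrical events
#'
#' Peaks are local maxima at least `prominence_mv` above the resting
#' potential (on a lightly smoothed trace); peaks closer together than the
#' grouping window are merged into a single event (a burst). Event onset
#' and end are the interpolated crossings of rest + 10% of the event
#' amplitude outside the first and last peak; event duration is their
#' difference. Each event is classified by [classify_event()] and, for
#' single-peak events, APD10/50/90 are measured.
#'
#' @param trace A [voltage_trace()].
#' @param prominence_mv Minimum peak height above rest, mV (default 10).
#' @param group_ms Peak-grouping window, ms (default 300).
#' @param min_sep_ms Minimum inter-peak separation, ms (default 10).
#' @param min_dip_mv Minimum trough depth (prominence) separating
#'   neighboring peaks, mV (default 3).
#' @param smooth_ms Running-mean smoothing before peak finding, ms
#'   (default 2).
#' @param rest Resting potential override; computed via
#'   [resting_potential()] when `NULL`.
#' @return An `ap_event_table` data.frame: per event `onset`, `end`
#'   (seconds), `event_duration` (ms), `n_peaks`, `max_amplitude` (mV
#'   above rest), `first_peak`, `last_peak` (s), `class`, `apd10`,
#'   `apd50`, `apd90` (ms; NA unless single). Attributes: `resting_vm`,
#'   `rate`.
#' @export
detect_events <- function(trace, prominence_mv = 10, group_ms = 300,
                          min_sep_ms = 10, min_dip_mv = 3, smooth_ms = 2,
                          rest = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$rate < 1000) stop("rate must be >= 1 kHz", call. = FALSE)
  if (is.null(rest)) rest <- resting_potential(trace)
  t <- trace$t
  k <- max(1L, as.integer(round(trace$rate * smooth_ms / 1000)))
  vs <- .runmean(trace$v, k)
  pk <- .find_peaks(vs, rest + prominence_mv,
                    as.integer(trace$rate * min_sep_ms / 1000),
                    min_dip_mv)
  empty <- data.frame(onset = numeric(0), end = numeric(0),
                      event_duration = numeric(0), n_peaks = integer(0),
                      max_amplitude = numeric(0), first_peak = numeric(0),
                      last_peak = numeric(0), class = character(0),
                      apd10 = numeric(0), apd50 = numeric(0),
                      apd90 = numeric(0))
  if (!length(pk)) {
    out <- empty
  } else {
    grp <- cumsum(c(1, diff(t[pk]) > group_ms / 1000))
    out <- do.call(rbind, lapply(split(pk, grp), function(p) {
      vmax <- max(vs[p])
      amp <- vmax - rest
      lvl <- rest + 0.1 * amp
      # onset: last upward crossing of lvl before the first peak
      i <- p[1]
      while (i > 1 && vs[i - 1] > lvl) i <- i - 1
      onset <- if (i > 1) .xing(t, vs, i - 1, lvl) else t[1]
      # end: first downward crossing of lvl after the last peak
      j <- p[length(p)]
      while (j < length(vs) && vs[j + 1] > lvl) j <- j + 1
      end <- if (j < length(vs)) .xing(t, vs, j, lvl) else t[length(t)]
      cls <- classify_event(length(p), t[p], vs[p] - rest)
      ap <- c(apd10 = NA_real_, apd50 = NA_real_, apd90 = NA_real_)
      if (cls == "single") {
        ap <- .apd_from_samples(t, vs, p[1], onset, rest, amp)
      }
      data.frame(onset = onset, end = end,
                 event_duration = (end - onset) * 1000,
                 n_peaks = length(p), max_amplitude = amp,
                 first_peak = t[p[1]], last_peak = t[p[length(p)]],
                 class = cls, apd10 = ap[1], apd50 = ap[2], apd90 = ap[3])
    }))
    rownames(out) <- NULL
  }
  attr(out, "resting_vm") <- rest
  attr(out, "rate") <- trace$rate
  class(out) <- c("ap_event_table", "data.frame")
  out
}

# APD_x measured from `ref_time` (event onset) to the first decaying-phase
# interpolated crossing of rest + (1 - x/100) * amplitude after the peak
.apd_from_samples <- function(t, v, i_peak, ref_time, rest, amp) {
  vapply(c(10, 50, 90), function(x) {
    lvl <- rest + (1 - x / 100) * amp
    j <- i_peak
    while (j < length(v) && v[j + 1] > lvl) j <- j + 1
    if (j >= length(v)) return(NA_real_)
    (.xing(t, v, j, lvl) - ref_time) * 1000
  }, 0)
}

#' Action-potential durations for one event
#'
#' APD10/50/90: time from the event onset (the 10%-amplitude upstroke
#' crossing) to the point where the membrane has repolarized by 10, 50 and
#' 90% of the event amplitude. Only meaningful for single-peak events;
#' multi-peak events return NAs. `ref = "peak"` measures from the peak
#' instead of the onset.
#'
#' @param trace A [voltage_trace()].
#' @param event One row of an `ap_event_table`.
#' @param rest Resting potential (default: the table attribute carried on
#'   the event's source, else recomputed).
#' @param ref `"onset"` (default) or `"peak"`.
#' @return Named numeric `c(apd10, apd50, apd90)` in ms.
#' @export
ap_durations <- function(trace, event, rest = NULL,
                         ref = c("onset", "peak")) {
  ref <- match.arg(ref)
  if (event$class != "single") {
    return(c(apd10 = NA_real_, apd50 = NA_real_, apd90 = NA_real_))
  }
  if (is.null(rest)) rest <- resting_potential(trace)
  i_peak <- which.min(abs(trace$t - event$first_peak))
  ref_time <- if (ref == "onset") event$onset else event$first_peak
  out <- .apd_from_samples(trace$t, trace$v, i_peak, ref_time, rest,
                           event$max_amplitude)
  names(out) <- c("apd10", "apd50", "apd90")
  out
}

#' Classify an electrical event
#'
#' `single` for one peak. Two peaks are an EAD double-peak when the second
#' rises during the repolarization of the first (inter-peak interval below
#' `ead_max_gap_s`) and stays below `full_amp_frac` of the first peak's
#' amplitude; otherwise two peaks count as a (two-full-amplitude-peak)
#' burst. Three or more peaks are always a burst.
#'
#' @param n_peaks Number of peaks in the event.
#' @param peak_times Peak times, seconds.
#' @param peak_heights Peak heights above rest, mV.
#' @param ead_max_gap_s Maximum inter-peak gap for an EAD (default 0.15).
#' @param full_amp_frac Fraction of the first peak's amplitude above which
#'   a second peak counts as full-amplitude (default 0.9).
#' @return `"single"`, `"ead_double"` or `"burst"`.
#' @export
classify_event <- function(n_peaks, peak_times, peak_heights,
                           ead_max_gap_s = 0.15, full_amp_frac = 0.9) {
  if (n_peaks == 1) return("single")
  if (n_peaks == 2) {
    gap <- peak_times[2] - peak_times[1]
    if (gap < ead_max_gap_s &&
        peak_heights[2] < full_amp_frac * peak_heights[1]) {
      return("ead_double")
    }
    return("burst")
  }
  "burst"
}

#' Per-record (per-fly) electrical summary
#'
#' Means over a representative stable window: resting potential, maximum
#' amplitude, peaks per burst, event duration, and APD10/50/90 averaged
#' over the single-peak APs. APD averages over fewer than `min_aps`
#' single APs are emitted with a warning (the convention is 20-50 APs per
#' fly).
#'
#' @param events An `ap_event_table` from [detect_events()].
#' @param duration_s Record duration, seconds; a warning is issued below
#'   `window_s`.
#' @param window_s Nominal analysis window, seconds (default 30).
#' @param min_aps Minimum single APs for an unflagged APD mean
#'   (default 20).
#' @return A named list: `resting_vm`, `n_events`, `mean_amplitude`,
#'   `mean_peaks_per_burst`, `mean_event_duration`, `n_single_aps`,
#'   `apd10`, `apd50`, `apd90`, `apd_below_minimum`.
#' @export
record_summary <- function(events, duration_s = NULL, window_s = 30,
                           min_aps = 20) {
  stopifnot(inherits(events, "data.frame"))
  if (!is.null(duration_s) && duration_s < window_s) {
    warning(sprintf("record (%.3g s) shorter than the %g s analysis window",
                    duration_s, window_s))
  }
  single <- events[events$class == "single", , drop = FALSE]
  below <- nrow(single) > 0 && nrow(single) < min_aps
  if (below) {
    warning(sprintf("APD means over only %d single APs (minimum %d)",
                    nrow(single), min_aps))
  }
  m <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
  list(resting_vm = attr(events, "resting_vm"),
       n_events = nrow(events),
       mean_amplitude = m(events$max_amplitude),
       mean_peaks_per_burst = m(events$n_peaks),
       mean_event_duration = m(events$event_duration),
       n_single_aps = nrow(single),
       apd10 = m(single$apd10), apd50 = m(single$apd50),
       apd90 = m(single$apd90),
       apd_below_minimum = below)
}
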