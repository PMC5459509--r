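#' Synthetic recording specification
#'
#' Builds a validated parameter set describing one synthetic heart recording:
#' the beat-interval distributions, wall diameters, contraction-phase
#' durations, action-potential statistics and noise level used by the
#' renderers. Presets encode the phenotype classes quantified in semi-intact
#' fly heart preparations: a regular young wildtype rhythm, a bradycardic
#' arrhythmic hERG/seizure-like rhythm, a burst-dominated KCNQ-like rhythm,
#' an aged wildtype with occasional triggered activity, and a viscous-load
#' condition with a doubled isometric phase.
#'
#' @param preset One of `"wt_young"`, `"sei_like"`, `"kcnq_like"`,
#'   `"wt_old"`, `"load"`. Sets every default below; any argument supplied
#'   explicitly overrides the preset value.
#' @param duration_s Recording length in seconds (default 30, the standard
#'   analysis window).
#' @param fps Optical sampling rate, frames per second.
#' @param ephys_rate Electrical sampling rate, samples per second.
#' @param di_dist,si_dist Length-2 numeric `(mean, sd)` in seconds for the
#'   diastolic and systolic interval distributions.
#' @param dd_um,sd_um Diastolic and systolic inner diameters, micrometers.
#' @param sp_s,iso_s,lp_s Nominal shortening / isometric / lengthening phase
#'   durations in seconds; scaled per beat to fill the realized SI.
#' @param ead_prob Probability that a non-burst AP carries a secondary (EAD)
#'   peak.
#' @param burst_prob Probability that an electrical event is a multi-peak
#'   burst.
#' @param peaks_per_burst_dist Length-2 `(mean, sd)` for burst peak counts.
#' @param rest_vm_mv Resting membrane potential, mV.
#' @param amp_mv Action-potential amplitude above rest, mV.
#' @param upstroke_s,repol_s AP upstroke and repolarization durations,
#'   seconds (single-peak waveform; burst constituents use a compressed
#'   repolarization).
#' @param burst_ibi_s Intra-burst inter-peak interval, seconds.
#' @param ap_latency_s Latency from AP onset to contraction onset, seconds.
#' @param noise_sd Additive Gaussian noise scale: micrometers on diameter
#'   traces, millivolts on voltage traces, fraction of intensity range on
#'   movie pixels.
#' @param seed Integer seed; every downstream draw is a deterministic
#'   function of the spec (including the seed).
#' @return An object of class `synth_spec` (a named list).
#' @examples
#' sp <- synth_spec("wt_young", seed = 1)
#' sp$di_dist
#' @export
synth_spec <- function(preset = c("wt_young", "sei_like", "kcnq_like",
                                  "wt_old", "load"),
                       duration_s = NULL, fps = NULL, ephys_rate = NULL,
                       di_dist = NULL, si_dist = NULL,
                       dd_um = NULL, sd_um = NULL,
                       sp_s = NULL, iso_s = NULL, lp_s = NULL,
                       ead_prob = NULL, burst_prob = NULL,
                       peaks_per_burst_dist = NULL,
                       rest_vm_mv = NULL, amp_mv = NULL,
                       upstroke_s = NULL, repol_s = NULL,
                       burst_ibi_s = NULL, ap_latency_s = NULL,
                       noise_sd = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- .flybeat_presets[[preset]]
  spec <- def
  override <- list(
    duration_s = duration_s, fps = fps, ephys_rate = ephys_rate,
    di_dist = di_dist, si_dist = si_dist, dd_um = dd_um, sd_um = sd_um,
    sp_s = sp_s, iso_s = iso_s, lp_s = lp_s,
    ead_prob = ead_prob, burst_prob = burst_prob,
    peaks_per_burst_dist = peaks_per_burst_dist,
    rest_vm_mv = rest_vm_mv, amp_mv = amp_mv,
    upstroke_s = upstroke_s, repol_s = repol_s,
    burst_ibi_s = burst_ibi_s, ap_latency_s = ap_latency_s,
    noise_sd = noise_sd)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) spec[[nm]] <- override[[nm]]
  }
  spec$preset <- preset
  spec$seed <- as.integer(seed)
  spec <- structure(spec, class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

# Preset tables. Interval ranges follow the young-wildtype convention
# (SI 0.2-0.28 s, DI 0.5-0.8 s in the denervated preparation); voltage
# presets follow typical intracellular values (rest -50..-35 mV, amplitude
# ~50 mV; burst-dominated KCNQ-like records average ~8 peaks per event,
# seizure-like records carry EAD double peaks and occasional short bursts).
.flybeat_presets <- list(
  wt_young = list(
    duration_s = 30, fps = 200, ephys_rate = 5000,
    di_dist = c(0.65, 0.05), si_dist = c(0.25, 0.02),
    dd_um = 80, sd_um = 60,
    sp_s = 0.10, iso_s = 0.03, lp_s = 0.12,
    ead_prob = 0.02, burst_prob = 0.02,
    peaks_per_burst_dist = c(3, 0.5),
    rest_vm_mv = -40, amp_mv = 49,
    upstroke_s = 0.004, repol_s = 0.12,
    burst_ibi_s = 0.12, ap_latency_s = 0,
    noise_sd = 1),
  sei_like = list(
    duration_s = 30, fps = 200, ephys_rate = 5000,
    di_dist = c(1.00, 0.35), si_dist = c(0.27, 0.03),
    dd_um = 70, sd_um = 60,
    sp_s = 0.13, iso_s = 0.02, lp_s = 0.12,
    ead_prob = 0.30, burst_prob = 0.15,
    peaks_per_burst_dist = c(3, 1),
    rest_vm_mv = -38.5, amp_mv = 53,
    upstroke_s = 0.004, repol_s = 0.16,
    burst_ibi_s = 0.12, ap_latency_s = 0,
    noise_sd = 1),
  kcnq_like = list(
    duration_s = 30, fps = 200, ephys_rate = 5000,
    di_dist = c(1.40, 0.30), si_dist = c(0.25, 0.02),
    dd_um = 80, sd_um = 62,
    sp_s = 0.10, iso_s = 0.03, lp_s = 0.12,
    ead_prob = 0.10, burst_prob = 0.80,
    peaks_per_burst_dist = c(8, 2),
    rest_vm_mv = -40.4, amp_mv = 53,
    upstroke_s = 0.004, repol_s = 0.12,
    burst_ibi_s = 0.12, ap_latency_s = 0,
    noise_sd = 1),
  wt_old = list(
    duration_s = 30, fps = 200, ephys_rate = 5000,
    di_dist = c(0.75, 0.15), si_dist = c(0.26, 0.02),
    dd_um = 78, sd_um = 61,
    sp_s = 0.10, iso_s = 0.03, lp_s = 0.13,
    ead_prob = 0.25, burst_prob = 0.10,
    peaks_per_burst_dist = c(3, 1),
    rest_vm_mv = -40, amp_mv = 50,
    upstroke_s = 0.004, repol_s = 0.14,
    burst_ibi_s = 0.12, ap_latency_s = 0,
    noise_sd = 1),
  # Viscous-load condition: isometric hold doubled relative to wt_young,
  # SI mean grown by the same amount so the phases still fill the SI.
  load = list(
    duration_s = 30, fps = 200, ephys_rate = 5000,
    di_dist = c(0.65, 0.05), si_dist = c(0.28, 0.02),
    dd_um = 80, sd_um = 60,
    sp_s = 0.10, iso_s = 0.06, lp_s = 0.12,
    ead_prob = 0.02, burst_prob = 0.02,
    peaks_per_burst_dist = c(3, 0.5),
    rest_vm_mv = -40, amp_mv = 49,
    upstroke_s = 0.004, repol_s = 0.12,
    burst_ibi_s = 0.12, ap_latency_s = 0,
    noise_sd = 1)
)

#' Validate a synth_spec
#'
#' Checks the structural invariants of a [synth_spec()]: positive durations
#' and rates, systolic diameter below diastolic, probabilities in `[0, 1]`,
#' phase durations no longer than the mean systolic interval, and positive
#' AP amplitude.
#'
#' @param spec A `synth_spec`.
#' @return `spec`, invisibly; errors otherwise.
#' @export
validate_synth_spec <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(spec$duration_s > 0, "duration_s must be > 0")
  chk(spec$fps > 0, "fps must be > 0")
  chk(spec$ephys_rate > 0, "ephys_rate must be > 0")
  chk(length(spec$di_dist) == 2 && spec$di_dist[1] > 0 && spec$di_dist[2] >= 0,
      "di_dist must be (mean > 0, sd >= 0)")
  chk(length(spec$si_dist) == 2 && spec$si_dist[1] > 0 && spec$si_dist[2] >= 0,
      "si_dist must be (mean > 0, sd >= 0)")
  chk(spec$sd_um < spec$dd_um, "sd_um must be < dd_um")
  chk(spec$sd_um > 0, "sd_um must be > 0")
  chk(all(spec$sp_s > 0, spec$iso_s >= 0, spec$lp_s > 0),
      "phase durations must be positive (iso may be 0)")
  chk(spec$sp_s + spec$iso_s + spec$lp_s <= spec$si_dist[1] + 1e-9,
      "sp_s + iso_s + lp_s must not exceed the mean SI")
  chk(spec$ead_prob >= 0 && spec$ead_prob <= 1, "ead_prob must be in [0,1]")
  chk(spec$burst_prob >= 0 && spec$burst_prob <= 1,
      "burst_prob must be in [0,1]")
  chk(spec$amp_mv > 0, "amp_mv must be > 0")
  chk(spec$noise_sd >= 0, "noise_sd must be >= 0")
  chk(is.finite(spec$seed), "seed must be a finite integer")
  invisible(spec)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> preset=%s  %.5gs @ %g fps / %g Hz ephys, seed=%d\n",
              x$preset, x$duration_s, x$fps, x$ephys_rate, x$seed))
  cat(sprintf("  DI ~ N(%.3g, %.3g) s   SI ~ N(%.3g, %.3g) s\n",
              x$di_dist[1], x$di_dist[2], x$si_dist[1], x$si_dist[2]))
  cat(sprintf("  DD %.3g um  SD %.3g um   SP/ISO/LP %.3g/%.3g/%.3g s\n",
              x$dd_um, x$sd_um, x$sp_s, x$iso_s, x$lp_s))
  cat(sprintf("  rest %.3g mV  amp %.3g mV  ead %.2g  burst %.2g  noise %.3g\n",
              x$rest_vm_mv, x$amp_mv, x$ead_prob, x$burst_prob, x$noise_sd))
  invisible(x)
}

# truncate interval draws at twice the frame period (shorter intervals are
# unresolvable optically and would make schedules degenerate)
.trunc_draw <- function(n, mean, sd, floor_s) {
  pmax(stats::rnorm(n, mean, sd), floor_s)
}

#' Generate a beat and AP-event schedule with exact ground truth
#'
#' Draws per-beat systolic and diastolic intervals from the spec
#' distributions (truncated at two frame periods), assigns contraction
#' onsets filling the recording, scales the three contraction phases to fill
#' each realized SI, and co-schedules one electrical event per beat whose
#' class (single / EAD double-peak / burst) is drawn from the spec
#' probabilities. All analytic event features (event duration, APD10/50/90
#' for single-peak events) are carried in the returned table and serve as
#' the test oracle.
#'
#' @param spec A [synth_spec()].
#' @return A `ground_truth` object: list with `beats` (data.frame: `onset`,
#'   `si`, `di`, `dd`, `sd`, `sp`, `iso`, `lp`), `ap_events` (data.frame:
#'   `onset`, `class`, `n_peaks`, `event_duration`, `apd10/50/90` in ms, NA
#'   for multi-peak events), `ttl_window`, and the generating `spec`.
#'   The record begins in diastole; `di[k]` is the interval following beat
#'   `k` (NA for the last beat).
#' @examples
#' gt <- make_beat_schedule(synth_spec("wt_young", duration_s = 10, seed = 1))
#' head(gt$beats)
#' @export
make_beat_schedule <- function(spec) {
  validate_synth_spec(spec)
  set.seed(spec$seed)
  floor_s <- 2 / spec$fps
  dur <- spec$duration_s

  # draw order (fixed for determinism): leading DI, then per beat SI, DI
  lead_di <- .trunc_draw(1, spec$di_dist[1], spec$di_dist[2], floor_s)
  onset <- lead_di
  beats <- list()
  k <- 0L
  repeat {
    si <- .trunc_draw(1, spec$si_dist[1], spec$si_dist[2], floor_s)
    if (onset + si > dur + 1e-12) break
    di <- .trunc_draw(1, spec$di_dist[1], spec$di_dist[2], floor_s)
    k <- k + 1L
    beats[[k]] <- c(onset = onset, si = si, di = di)
    onset <- onset + si + di
  }
  if (k == 0L) {
    stop("duration_s too short to schedule a single beat", call. = FALSE)
  }
  b <- as.data.frame(do.call(rbind, beats))
  b$di[k] <- NA_real_  # last beat's following interval is right-censored

  # phases scaled per beat so SP+ISO+LP fills the realized SI exactly
  ph_sum <- spec$sp_s + spec$iso_s + spec$lp_s
  b$sp <- spec$sp_s * b$si / ph_sum
  b$iso <- spec$iso_s * b$si / ph_sum
  b$lp <- spec$lp_s * b$si / ph_sum
  b$dd <- spec$dd_um
  b$sd <- spec$sd_um

  ev <- .schedule_ap_events(b, spec)

  structure(list(beats = b[, c("onset", "si", "di", "dd", "sd",
                               "sp", "iso", "lp")],
                 ap_events = ev,
                 ttl_window = c(0, dur),
                 spec = spec),
            class = "ground_truth")
}

# One electrical event per beat; class and shape drawn here so renderers
# and ground truth share the identical analytic waveform parameters.
.schedule_ap_events <- function(b, spec) {
  n <- nrow(b)
  u <- spec$upstroke_s
  cls_draw <- stats::runif(n)
  is_burst <- cls_draw < spec$burst_prob
  is_ead <- !is_burst & (cls_draw < spec$burst_prob +
                           (1 - spec$burst_prob) * spec$ead_prob)
  cls <- ifelse(is_burst, "burst", ifelse(is_ead, "ead_double", "single"))
  n_peaks <- rep(1L, n)
  n_peaks[is_ead] <- 2L
  n_peaks[is_burst] <- pmax(3L, as.integer(round(
    stats::rnorm(sum(is_burst), spec$peaks_per_burst_dist[1],
                 spec$peaks_per_burst_dist[2]))))
  # EAD geometry: a narrow bump (half-width 3% of repolarization) at
  # 50-60% of repolarization, 12-18% of amplitude above the local decay
  # line: a genuine second maximum with a detectable trough on both sides
  ead_frac <- stats::runif(n, 0.50, 0.60)
  ead_bump <- stats::runif(n, 0.12, 0.18)

  onset_ap <- b$onset - spec$ap_latency_s
  # cap burst length so events never overlap the next event's onset
  gap_to_next <- c(diff(onset_ap), Inf)
  repol_burst <- spec$repol_s * 0.6
  for (i in which(is_burst)) {
    # keep bursts clear of the next event by more than the event-grouping
    # window (300 ms), so scheduled events stay distinct after analysis
    max_extent <- gap_to_next[i] - 0.35
    fit <- floor((max_extent - u - repol_burst) / spec$burst_ibi_s) + 1
    fit <- min(fit, 10000)
    n_peaks[i] <- max(3L, min(n_peaks[i], as.integer(fit)))
  }

  ev <- data.frame(onset = onset_ap, class = cls, n_peaks = n_peaks,
                   ead_frac = ead_frac, ead_bump = ead_bump,
                   stringsAsFactors = FALSE)
  ev$ead_frac[!is_ead] <- NA_real_
  ev$ead_bump[!is_ead] <- NA_real_

  # analytic features at the rest + 10%-amplitude level of the linear
  # upstroke/repolarization waveform (see render_voltage_trace)
  t_on10 <- 0.1 * u          # upstroke crossing of the 10% level
  t_end_single <- u + 0.9 * spec$repol_s  # decay crossing of the 10% level
  ev$event_duration <- NA_real_
  ev$apd10 <- ev$apd50 <- ev$apd90 <- NA_real_
  single <- cls == "single"
  ev$event_duration[single] <- (t_end_single - t_on10) * 1000
  # APD_x: onset (10% upstroke) to decay crossing of rest + (1 - x/100)*amp
  ev$apd10[single] <- (0.9 * u + 0.10 * spec$repol_s) * 1000
  ev$apd50[single] <- (0.9 * u + 0.50 * spec$repol_s) * 1000
  ev$apd90[single] <- (0.9 * u + 0.90 * spec$repol_s) * 1000
  ead <- cls == "ead_double"
  # EAD event ends when the (unmodified) primary decay crosses the 10% level
  ev$event_duration[ead] <- (t_end_single - t_on10) * 1000
  burst <- cls == "burst"
  ev$event_duration[burst] <-
    ((ev$n_peaks[burst] - 1) * spec$burst_ibi_s + u +
       0.9 * repol_burst - t_on10) * 1000
  ev
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats, %d AP events, ttl [%.3g, %.3g) s\n",
              nrow(x$beats), nrow(x$ap_events),
              x$ttl_window[1], x$ttl_window[2]))
  invisible(x)
}
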