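# Renderers: turn a ground_truth schedule into diameter traces, voltage
# traces, synchronized pairs and grayscale movies. All waveforms are
# piecewise linear so that every ground-truth quantity is analytic.

#' Render a diameter trace from a beat schedule
#'
#' Each beat is a piecewise-linear excursion from the diastolic plateau:
#' a linear shortening ramp over SP down to the systolic diameter, a flat
#' isometric hold over ISO, and a linear lengthening ramp over LP back to
#' the plateau. Gaussian noise of scale `spec$noise_sd` (micrometers) is
#' added on top; uniform sampling at `spec$fps`.
#'
#' @param gt A [make_beat_schedule()] ground truth.
#' @param spec The generating [synth_spec()] (defaults to `gt$spec`).
#' @return A [diameter_trace()].
#' @export
render_diameter_trace <- function(gt, spec = gt$spec) {
  stopifnot(inherits(gt, "ground_truth"))
  if (spec$fps < 50) stop("fps must be >= 50 for diameter rendering",
                          call. = FALSE)
  b <- gt$beats
  bad <- b$sp + b$iso + b$lp > b$si + 1e-9
  if (any(bad)) stop("phase durations exceed SI for beat(s) ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  n <- round(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1) / spec$fps

  # knots of the piecewise-linear waveform
  kx <- c(0, as.vector(rbind(b$onset,
                             b$onset + b$sp,
                             b$onset + b$sp + b$iso,
                             b$onset + b$sp + b$iso + b$lp)),
          spec$duration_s)
  ky <- c(b$dd[1], as.vector(rbind(b$dd, b$sd, b$sd, b$dd)),
          b$dd[nrow(b)])
  d <- stats::approx(kx, ky, xout = t, rule = 2, ties = "ordered")$y
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 1L)
    d <- d + stats::rnorm(n, 0, spec$noise_sd)
  }
  diameter_trace(t, d, spec$fps, provenance = paste0("synthetic:", spec$preset))
}

# Piecewise-linear knot list (times relative to event onset, values as a
# fraction of AP amplitude) for one electrical event. Shared by the
# renderer and by the scheduled analytic features.
.ap_event_knots <- function(ev, spec) {
  u <- spec$upstroke_s
  R <- spec$repol_s
  if (ev$class == "single") {
    list(x = c(0, u, u + R), y = c(0, 1, 0))
  } else if (ev$class == "ead_double") {
    f <- ev$ead_frac
    bump <- ev$ead_bump
    ctr <- u + f * R
    w <- 0.03 * R
    decay <- function(tt) 1 - (tt - u) / R
    list(x = c(0, u, ctr - w, ctr, ctr + w, u + R),
         y = c(0, 1, decay(ctr - w), decay(ctr) + bump, decay(ctr + w), 0))
  } else {  # burst
    ibi <- spec$burst_ibi_s
    Rb <- 0.6 * R
    np <- ev$n_peaks
    xs <- c(0, u)
    ys <- c(0, 1)
    if (np > 1) {
      for (p in seq_len(np - 1)) {
        tp <- u + (p - 1) * ibi
        xs <- c(xs, tp + 0.6 * ibi, tp + ibi)
        ys <- c(ys, 0.25, 1)         # partial repolarization between peaks
      }
    }
    last <- u + (np - 1) * ibi
    xs <- c(xs, last + Rb)
    ys <- c(ys, 0)
    list(x = xs, y = ys)
  }
}

#' Render an intracellular voltage trace from a schedule
#'
#' Baseline at the resting potential; each scheduled event is rendered as a
#' class-dependent piecewise-linear waveform: a single action potential
#' (fast upstroke to rest + amplitude, linear repolarization), an EAD
#' double-peak (a secondary depolarization riding the repolarization), or a
#' burst of partial-repolarization peaks at the intra-burst interval.
#' Ground truth carries the analytic APD10/50/90 for single-peak events.
#'
#' @param gt A [make_beat_schedule()] ground truth.
#' @param spec The generating [synth_spec()] (defaults to `gt$spec`).
#' @param t0 Electrical time at which the schedule's time zero falls
#'   (seconds); used when embedding the movie window in a longer record.
#' @param total_s Total electrical record length (default: schedule
#'   duration plus `t0`).
#' @param ttl_window Optional `c(on, off)`: renders an auxiliary TTL
#'   channel high exactly on `[on, off)`.
#' @return A [voltage_trace()].
#' @export
render_voltage_trace <- function(gt, spec = gt$spec, t0 = 0,
                                 total_s = spec$duration_s + t0,
                                 ttl_window = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (spec$ephys_rate < 2000) {
    stop("ephys_rate must be >= 2 kHz", call. = FALSE)
  }
  if (spec$amp_mv <= 0) stop("amp_mv must be > 0", call. = FALSE)
  n <- round(total_s * spec$ephys_rate)
  t <- (seq_len(n) - 1) / spec$ephys_rate

  ev <- gt$ap_events
  kx <- 0
  ky <- 0
  for (i in seq_len(nrow(ev))) {
    kn <- .ap_event_knots(ev[i, ], spec)
    kx <- c(kx, ev$onset[i] + t0 + kn$x)
    ky <- c(ky, kn$y)
  }
  kx <- c(kx, total_s)
  ky <- c(ky, 0)
  ord <- order(kx)
  shape <- stats::approx(kx[ord], ky[ord], xout = t, rule = 2,
                         ties = "ordered")$y
  v <- spec$rest_vm_mv + spec$amp_mv * shape
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 2L)
    v <- v + stats::rnorm(n, 0, spec$noise_sd)
  }
  aux <- NULL
  if (!is.null(ttl_window)) {
    aux <- as.numeric(t >= ttl_window[1] & t < ttl_window[2]) * 5
  }
  voltage_trace(t, v, spec$ephys_rate, aux = aux)
}

#' Render a synchronized optical + electrical pair
#'
#' Emits a voltage trace whose auxiliary TTL channel is high exactly during
#' the movie interval, together with the diameter trace on the movie clock.
#' Each contraction onset is co-scheduled with an AP-event onset separated
#' by the fixed `spec$ap_latency_s`.
#'
#' @param gt A [make_beat_schedule()] ground truth.
#' @param spec The generating [synth_spec()] (defaults to `gt$spec`).
#' @param pad_s Electrical record padding before and after the movie
#'   window, seconds.
#' @return A `sync_pair`: list with `voltage` ([voltage_trace()] with TTL
#'   aux), `optical` ([diameter_trace()]), `offset` (electrical time of
#'   optical frame 0) and `window` (`c(on, off)` on the electrical clock).
#' @export
render_sync_pair <- function(gt, spec = gt$spec, pad_s = 2) {
  stopifnot(inherits(gt, "ground_truth"), pad_s >= 0)
  win <- c(pad_s, pad_s + spec$duration_s)
  voltage <- render_voltage_trace(gt, spec, t0 = pad_s,
                                  total_s = spec$duration_s + 2 * pad_s,
                                  ttl_window = win)
  optical <- render_diameter_trace(gt, spec)
  structure(list(voltage = voltage, optical = optical,
                 offset = win[1], window = win, ground_truth = gt),
            class = "sync_pair")
}

#' @export
print.sync_pair <- function(x, ...) {
  cat(sprintf("<sync_pair> TTL window [%.3g, %.3g) s, offset %.3g s\n",
              x$window[1], x$window[2], x$offset))
  print(x$voltage)
  print(x$optical)
  invisible(x)
}

#' Render a grayscale movie of the beating heart tube
#'
#' Frames show two dark wall bands symmetric about a horizontal tube axis,
#' separated by the instantaneous trace diameter, over a brighter
#' background with an intermediate-intensity lumen. Edges are
#' area-antialiased (each pixel integrates the ideal profile over its
#' extent). Gaussian "photon" noise of scale `2% of range x spec$noise_sd`
#' is added per pixel.
#'
#' @param trace A [diameter_trace()].
#' @param geometry List: `height_px`, `width_px`, `um_per_px`, `wall_um`
#'   (wall band thickness), optional `center_row` (0-based; default frame
#'   middle).
#' @param spec A [synth_spec()] supplying `noise_sd` and `seed`.
#' @return A [frame_stack()].
#' @export
render_movie <- function(trace,
                         geometry = list(height_px = 120, width_px = 16,
                                         um_per_px = 1, wall_um = 8),
                         spec = NULL) {
  stopifnot(inherits(trace, "diameter_trace"))
  g <- geometry
  if (is.null(g$center_row)) g$center_row <- (g$height_px - 1) / 2
  scale <- g$um_per_px
  r_px <- (trace$d / 2) / scale
  t_px <- g$wall_um / scale
  if (any(2 * (r_px + t_px) >= g$height_px - 2)) {
    stop("diameter (plus wall bands) exceeds frame height", call. = FALSE)
  }
  bg <- 0.85; wall <- 0.15; lumen <- 0.65
  n <- length(trace$d)
  y <- seq_len(g$height_px) - 1  # 0-based pixel centers
  lo <- y - 0.5; hi <- y + 0.5
  ov <- function(a, b) pmax(0, pmin(hi, b) - pmax(lo, a))  # overlap length
  frames <- array(0, dim = c(g$height_px, g$width_px, n))
  c0 <- g$center_row
  for (j in seq_len(n)) {
    r <- r_px[j]
    cov_lumen <- ov(c0 - r, c0 + r)
    cov_wall <- ov(c0 - r - t_px, c0 - r) + ov(c0 + r, c0 + r + t_px)
    profile <- bg * (1 - cov_lumen - cov_wall) +
      lumen * cov_lumen + wall * cov_wall
    frames[, , j] <- profile
  }
  if (!is.null(spec) && spec$noise_sd > 0) {
    set.seed(spec$seed + 3L)
    frames <- frames + array(
      stats::rnorm(length(frames), 0, 0.02 * spec$noise_sd), dim(frames))
  }
  frame_stack(frames, trace$fps, scale)
}
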