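# Beat segmentation and headline cardiac parameters: DI, SI, heart period,
# arrhythmia index, diastolic/systolic diameters, fractional shortening and
# binned DI histograms.

# rolling quantile of d over a time window, evaluated on a coarse grid and
# linearly interpolated back onto t (cheap, smooth)
.rolling_quantile <- function(t, d, window_s, q, grid_s = 0.25) {
  gx <- seq(t[1], t[length(t)], by = grid_s)
  if (length(gx) < 2) gx <- c(t[1], t[length(t)])
  half <- window_s / 2
  gy <- vapply(gx, function(g) {
    stats::quantile(d[t >= g - half & t <= g + half], q, names = FALSE)
  }, 0)
  stats::approx(gx, gy, xout = t, rule = 2)$y
}

# least-squares line fit on a limb segment, extrapolated to level `b`;
# returns the crossing time, or NA if the segment is unusable
.limb_crossing <- function(t, d, idx, b) {
  if (length(idx) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, t[idx]), d[idx])
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || abs(slope) < 1e-9) return(NA_real_)
  (b - fit$coefficients[1]) / slope
}

# index window of the descending (-1) or ascending (+1) limb of a beat:
# the stretch of the smoothed trace between the 80% and 20% depth levels
# nearest the trough index
.limb_window <- function(ds, i_min, band_lo, band_hi, direction, i_edge) {
  if (direction < 0) {
    cand <- i_edge:i_min
    j_hi <- cand[ds[cand] >= band_hi]
    if (!length(j_hi)) return(integer(0))
    j_hi <- max(j_hi)
    j_lo <- j_hi:i_min
    j_lo <- j_lo[ds[j_lo] <= band_lo]
    if (!length(j_lo)) return(integer(0))
    j_hi:min(j_lo)
  } else {
    cand <- i_min:i_edge
    j_hi <- cand[ds[cand] >= band_hi]
    if (!length(j_hi)) return(integer(0))
    j_hi <- min(j_hi)
    j_lo <- i_min:j_hi
    j_lo <- j_lo[ds[j_lo] <= band_lo]
    if (!length(j_lo)) return(integer(0))
    max(j_lo):j_hi
  }
}

#' Segment a diameter trace into beats
#'
#' Hysteresis detection on the diameter relative to a rolling diastolic
#' baseline: a contraction is triggered by a downward crossing of the high
#' threshold (default 90% of the local baseline), confirmed by a deeper
#' excursion below the hysteresis level, and closed by the upward
#' re-crossing of the high threshold. Contraction onset and relaxation end
#' are then refined to sub-frame precision by fitting a line to the
#' mid-portion (20-80% of beat depth) of the descending and ascending
#' limbs and extrapolating it to the baseline level. Partial beats at the
#' record edges are discarded.
#'
#' @param trace A [diameter_trace()].
#' @param thr_frac High threshold as a fraction of the local diastolic
#'   baseline (default 0.9).
#' @param baseline_window_s Rolling-baseline window, seconds (default 2).
#' @param baseline_q Upper quantile defining the diastolic baseline
#'   (default 0.95).
#' @param hysteresis_frac Fraction of the local beat depth that must be
#'   reached to confirm a contraction (default 0.75).
#' @param min_depth_um Minimum baseline-to-trough depth for the record to
#'   count as beating at all (default 2 um).
#' @return A `beat_table` data.frame: `onset`, `relaxation_end`, `si`,
#'   `di`, `hp`, `dd`, `sd` (one row per complete beat; `di`/`hp` are NA
#'   for the last beat).
#' @export
segment_beats <- function(trace, thr_frac = 0.9, baseline_window_s = 2,
                          baseline_q = 0.95, hysteresis_frac = 0.75,
                          min_depth_um = 2) {
  stopifnot(inherits(trace, "diameter_trace"))
  t <- trace$t; d <- trace$d
  n <- length(t)
  if (n < 4) stop("trace too short", call. = FALSE)
  dt <- diff(t)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("trace is not uniformly sampled", call. = FALSE)
  }
  if (t[n] - t[1] < 2) stop("trace must cover at least 2 s", call. = FALSE)

  B <- .rolling_quantile(t, d, baseline_window_s, baseline_q)
  L <- .rolling_quantile(t, d, baseline_window_s, 1 - baseline_q)
  depth <- B - L
  empty <- data.frame(onset = numeric(0), relaxation_end = numeric(0),
                      si = numeric(0), di = numeric(0), hp = numeric(0),
                      dd = numeric(0), sd = numeric(0))
  class(empty) <- c("beat_table", "data.frame")
  if (max(depth) < min_depth_um) {
    warning("no beats detected (trace depth below minimum)")
    return(empty)
  }

  ds <- .runmean(d, 3)  # light smoothing for threshold crossings only
  thr_hi <- thr_frac * B
  thr_lo <- B - hysteresis_frac * depth

  # hysteresis state machine over samples; a closed beat is only committed
  # once the trace re-arms near the baseline (release level), so noise dips
  # on the rising limb extend the current beat instead of spawning a new one
  below_hi <- ds < thr_hi
  release <- B - 0.25 * depth
  state <- 0L  # 0 diastole, 1 tentative, 2 confirmed, 3 closed/refractory
  i_down <- NA_integer_
  i_up <- NA_integer_
  windows <- list()
  commit <- function(a, b) windows[[length(windows) + 1L]] <<- c(a, b)
  for (i in seq_len(n)) {
    if (state == 0L) {
      if (below_hi[i]) { state <- 1L; i_down <- i }
    } else if (state == 1L) {
      if (ds[i] < thr_lo[i]) state <- 2L
      else if (!below_hi[i]) state <- 0L  # shallow dip: noise
    } else if (state == 2L) {
      if (!below_hi[i]) { state <- 3L; i_up <- i }
    } else {  # refractory: waiting for re-arm
      if (ds[i] >= release[i]) {
        commit(i_down, i_up); state <- 0L
      } else if (below_hi[i]) {
        state <- 2L                        # rebound: same beat continues
      }
    }
  }
  if (state == 3L) commit(i_down, i_up)
  if (!length(windows)) {
    warning("no beats detected")
    return(empty)
  }

  fps <- trace$fps
  nw <- length(windows)
  wmat <- do.call(rbind, windows)

  # per-gap diastolic plateau levels (trimmed mean of inter-beat samples);
  # plateau[k] precedes beat k, plateau[nw + 1] follows the last beat
  plateau <- vapply(seq_len(nw + 1L), function(k) {
    lo <- if (k == 1L) 1L else wmat[k - 1L, 2]
    hi <- if (k > nw) n else wmat[k, 1]
    if (hi <= lo) return(NA_real_)
    idx <- lo:hi
    trim <- max(1L, as.integer(0.15 * length(idx)))
    idx <- idx[seq(trim, length(idx) - trim + 1L)]
    if (!length(idx)) idx <- lo:hi
    mean(d[idx])
  }, 0)
  # fall back to the rolling baseline where a gap was degenerate
  plateau[!is.finite(plateau)] <-
    B[pmin(n, wmat[pmin(nw, which(!is.finite(plateau))), 1])]

  beats <- lapply(seq_len(nw), function(k) {
    i0 <- wmat[k, 1]; i1 <- wmat[k, 2]
    seg <- i0:i1
    i_min <- seg[which.min(ds[seg])]
    b_pre <- plateau[k]
    b_post <- plateau[k + 1L]
    trough <- min(ds[seg])
    dep <- b_pre - trough
    band_lo <- trough + 0.12 * dep
    band_hi <- trough + 0.88 * dep
    # search region extends one SP-scale margin before/after the window
    m <- max(3L, as.integer(0.3 * fps))
    desc <- .limb_window(ds, i_min, band_lo, band_hi, -1L, max(1L, i0 - m))
    asc <- .limb_window(ds, i_min, band_lo, band_hi, +1L, min(n, i1 + m))
    onset <- .limb_crossing(t, ds, desc, b_pre)
    rel_end <- .limb_crossing(t, ds, asc, b_post)
    if (!is.finite(onset)) onset <- t[i0]          # fall back to crossing
    if (!is.finite(rel_end)) rel_end <- t[i1]
    # clamp refinement to the observation window (guards noisy fits)
    onset <- min(max(onset, t[max(1L, i0 - m)]), t[i_min])
    rel_end <- max(min(rel_end, t[min(n, i1 + m)]), t[i_min])
    c(onset = onset, relaxation_end = rel_end, i0 = i0, i1 = i1,
      i_min = i_min, sd = trough)
  })
  bm <- as.data.frame(do.call(rbind, beats))
  # discard partial beats touching the record edges
  keep <- bm$onset > t[1] & bm$relaxation_end < t[n]
  bm <- bm[keep, , drop = FALSE]
  if (!nrow(bm)) {
    warning("no complete beats inside the record")
    return(empty)
  }

  nb <- nrow(bm)
  out <- data.frame(onset = bm$onset, relaxation_end = bm$relaxation_end)
  out$si <- out$relaxation_end - out$onset
  out$di <- c(out$onset[-1], NA) - out$relaxation_end
  out$di[nb] <- NA
  out$hp <- c(diff(out$onset), NA)
  # per-beat diastolic plateau: trimmed mean of the pre-onset interval
  sm <- .runmean(d, 3)
  out$dd <- vapply(seq_len(nb), function(k) {
    lo_t <- if (k == 1) t[1] else out$relaxation_end[k - 1]
    hi_t <- out$onset[k]
    span <- hi_t - lo_t
    idx <- which(t >= lo_t + 0.15 * span & t <= hi_t - 0.15 * span)
    if (!length(idx)) idx <- which(t >= lo_t & t <= hi_t)
    mean(d[idx])
  }, 0)
  out$sd <- vapply(seq_len(nb), function(k) {
    idx <- bm$i0[k]:bm$i1[k]
    min(sm[idx])
  }, 0)
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Summarize a beat table
#'
#' Computes the headline per-record cardiac parameters: mean diastolic and
#' systolic intervals, median heart period, arrhythmia index (sample
#' standard deviation of heart periods normalized to the median heart
#' period), mean diastolic and systolic diameters, and fractional
#' shortening `(DD - SD) / DD`.
#'
#' @param bt A `beat_table` from [segment_beats()].
#' @return A `cardiac_summary` (named list): `n_beats`, `mean_di`,
#'   `mean_si`, `median_hp`, `ai`, `dd`, `sd`, `fs`. `ai` is `NA` (absent,
#'   not zero) with fewer than 3 beats.
#' @examples
#' bt <- data.frame(onset = c(0, 1, 2.2, 3.2), relaxation_end = c(.25, 1.25, 2.45, 3.45))
#' bt$si <- bt$relaxation_end - bt$onset
#' bt$di <- c(diff(bt$onset), NA) - bt$si
#' bt$hp <- c(diff(bt$onset), NA); bt$dd <- 80; bt$sd <- 60
#' class(bt) <- c("beat_table", "data.frame")
#' summarize_beats(bt)$ai
#' @export
summarize_beats <- function(bt) {
  stopifnot(inherits(bt, "data.frame"))
  hp <- bt$hp[is.finite(bt$hp)]
  ai <- if (nrow(bt) >= 3 && length(hp) >= 2) {
    stats::sd(hp) / stats::median(hp)
  } else NA_real_
  dd <- mean(bt$dd)
  sdm <- mean(bt$sd)
  structure(list(
    n_beats = nrow(bt),
    mean_di = mean(bt$di, na.rm = TRUE),
    mean_si = mean(bt$si),
    median_hp = if (length(hp)) stats::median(hp) else NA_real_,
    ai = ai,
    dd = dd,
    sd = sdm,
    fs = (dd - sdm) / dd
  ), class = "cardiac_summary")
}

#' @export
print.cardiac_summary <- function(x, ...) {
  cat(sprintf(
    "<cardiac_summary> %d beats | DI %.3g s  SI %.3g s  HP(med) %.3g s  AI %s\n",
    x$n_beats, x$mean_di, x$mean_si, x$median_hp,
    if (is.na(x$ai)) "NA" else sprintf("%.3g", x$ai)))
  cat(sprintf("  DD %.4g um  SD %.4g um  FS %.3g\n", x$dd, x$sd, x$fs))
  invisible(x)
}

#' Binned diastolic-interval histogram
#'
#' Pools DIs across hearts and bins them into uniform-width bins
#' `[k*w, (k+1)*w)`, expressed as a percentage of total DIs.
#'
#' @param tables A `beat_table` or list of beat tables.
#' @param bin_width Bin width in seconds (default 0.1).
#' @return A `di_histogram`: list with `bin_edges` (length bins + 1),
#'   `percent` per bin, `counts`, and `n_total`.
#' @export
di_histogram <- function(tables, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (inherits(tables, "data.frame")) tables <- list(tables)
  dis <- unlist(lapply(tables, function(b) b$di))
  dis <- dis[is.finite(dis)]
  if (!length(dis)) stop("no diastolic intervals to pool", call. = FALSE)
  kmax <- floor(max(dis) / bin_width)
  edges <- (0:(kmax + 1)) * bin_width
  counts <- vapply(seq_len(kmax + 1), function(k) {
    sum(dis >= edges[k] & dis < edges[k + 1])
  }, 0L)
  structure(list(bin_edges = edges,
                 percent = 100 * counts / length(dis),
                 counts = counts, n_total = length(dis)),
            class = "di_histogram")
}

#' @export
print.di_histogram <- function(x, ...) {
  cat(sprintf("<di_histogram> %d DIs in %d bins of %.3g s; modal bin [%.2g, %.2g) s (%.1f%%)\n",
              x$n_total, length(x$percent),
              diff(x$bin_edges[1:2]),
              x$bin_edges[which.max(x$percent)],
              x$bin_edges[which.max(x$percent) + 1],
              max(x$percent)))
  invisible(x)
}

#' Paired pre/post drug comparison
#'
#' Compares per-heart beat tables recorded before and after an exposure
#' (drug or vehicle): per-heart change in mean DI and beat count, cohort
#' mean +/- SEM at each timepoint, pooled DI histograms, and a flag on the
#' total beat count (bradycardic exposures sharply reduce the number of
#' beats in a fixed recording window).
#'
#' @param pre,post Named lists of `beat_table`s; names are heart IDs and
#'   must match between the two timepoints.
#' @param bin_width Histogram bin width in seconds.
#' @return A `pre_post_report`: list with `per_heart` (data.frame),
#'   `summary` (means and SEMs), `hist_pre`, `hist_post`, `n_ratio`
#'   (total beats post / pre).
#' @export
compare_pre_post <- function(pre, post, bin_width = 0.1) {
  if (is.null(names(pre)) || is.null(names(post))) {
    stop("pre and post must be named lists keyed by heart ID", call. = FALSE)
  }
  mismatch <- c(setdiff(names(pre), names(post)),
                setdiff(names(post), names(pre)))
  if (length(mismatch)) {
    stop("unpaired heart IDs: ", paste(unique(mismatch), collapse = ", "),
         call. = FALSE)
  }
  ids <- names(pre)
  per <- do.call(rbind, lapply(ids, function(id) {
    a <- pre[[id]]; b <- post[[id]]
    data.frame(heart = id,
               di_pre = mean(a$di, na.rm = TRUE),
               di_post = mean(b$di, na.rm = TRUE),
               n_pre = nrow(a), n_post = nrow(b))
  }))
  per$delta_di <- per$di_post - per$di_pre
  per$delta_n <- per$n_post - per$n_pre
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  n_pre_tot <- sum(per$n_pre); n_post_tot <- sum(per$n_post)
  structure(list(
    per_heart = per,
    summary = list(mean_di_pre = mean(per$di_pre), sem_di_pre = sem(per$di_pre),
                   mean_di_post = mean(per$di_post), sem_di_post = sem(per$di_post),
                   mean_delta_di = mean(per$delta_di), sem_delta_di = sem(per$delta_di)),
    hist_pre = di_histogram(pre, bin_width),
    hist_post = di_histogram(post, bin_width),
    n_ratio = n_post_tot / n_pre_tot,
    beat_count_reduced = n_post_tot < 0.8 * n_pre_tot
  ), class = "pre_post_report")
}

#' @export
print.pre_post_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pre_post_report> %d hearts | DI %.3g+/-%.3g -> %.3g+/-%.3g s (delta %.3g)\n",
              nrow(x$per_heart), s$mean_di_pre, s$sem_di_pre,
              s$mean_di_post, s$sem_di_post, s$mean_delta_di))
  cat(sprintf("  beat count ratio post/pre = %.3g%s\n", x$n_ratio,
              if (x$beat_count_reduced) " (reduced)" else ""))
  invisible(x)
}
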