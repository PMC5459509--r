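# Contraction-phase parsing: shortening / isometric / lengthening phases
# via a movable speed threshold, shortening velocity, and the
# pre/load/post viscous-load protocol report.

#' Wall-movement speed trace
#'
#' Absolute wall-movement speed `|dd/dt|` by central differences, with an
#' optional running-mean pre-smoothing of the diameter. The default is no
#' extra smoothing (the central difference already spans two frame
#' periods); noisy traces benefit from `smooth_window = 5`.
#'
#' @param trace A [diameter_trace()].
#' @param smooth_window Running-mean window (samples) applied to the
#'   diameter before differencing; 1 disables.
#' @return A `speed_trace`: list with `t`, `s` (um/s), `fps`.
#' @export
movement_trace <- function(trace, smooth_window = 1) {
  stopifnot(inherits(trace, "diameter_trace"))
  d <- .runmean(trace$d, smooth_window)
  n <- length(d)
  dt <- 1 / trace$fps
  s <- numeric(n)
  s[2:(n - 1)] <- abs(d[3:n] - d[1:(n - 2)]) / (2 * dt)
  s[1] <- abs(d[2] - d[1]) / dt
  s[n] <- abs(d[n] - d[n - 1]) / dt
  structure(list(t = trace$t, s = s, fps = trace$fps),
            class = "speed_trace")
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("<speed_trace> %d samples @ %g fps, peak %.4g um/s\n",
              length(x$s), x$fps, max(x$s)))
  invisible(x)
}

#' Parse contractions into shortening / isometric / lengthening phases
#'
#' Within each beat, supra-threshold movement-speed episodes are found
#' (half-open index runs). The first episode (the contraction speed peak)
#' is the shortening phase SP, the last episode (the relaxation speed
#' peak) is the lengthening phase LP, and the sub-threshold span between
#' them, at minimum diameter, is the isometric phase ISO. Beats with fewer
#' than two supra-threshold episodes are flagged (ISO undefined).
#'
#' The threshold is the movable bar of the interactive instrument: either
#' relative (a fraction of the per-beat peak speed, default 0.15) or an
#' absolute speed in um/s.
#'
#' @param speed A [movement_trace()] speed trace.
#' @param bt A `beat_table` from [segment_beats()].
#' @param threshold Numeric threshold value.
#' @param type `"relative"` (fraction of per-beat peak speed) or
#'   `"absolute"` (um/s).
#' @return A `phase_table` data.frame: per beat `sp`, `iso`, `lp`
#'   (seconds), `shortening_velocity` (um/s, `(DD - SD) / SP`),
#'   `threshold_um_s` (the absolute threshold used), `flagged`.
#' @export
parse_phases <- function(speed, bt, threshold = 0.15,
                         type = c("relative", "absolute")) {
  stopifnot(inherits(speed, "speed_trace"), inherits(bt, "data.frame"))
  type <- match.arg(type)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (speed$fps < 150) {
    warning("frame rate below 150 fps: phase durations will be coarse")
  }
  dt <- 1 / speed$fps
  out <- lapply(seq_len(nrow(bt)), function(k) {
    idx <- which(speed$t >= bt$onset[k] & speed$t < bt$relaxation_end[k])
    if (length(idx) < 3) {
      return(c(sp = NA, iso = NA, lp = NA, thr = NA, flagged = 1))
    }
    s <- speed$s[idx]
    thr <- if (type == "relative") threshold * max(s) else threshold
    above <- s >= thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ep <- which(r$values)
    # episode boundaries: interpolated crossings of max(threshold, half the
    # episode peak). The half-peak floor cancels the one-sample skirt that
    # central differencing smears onto each side of a speed plateau, so
    # noise-free piecewise-linear beats are recovered exactly.
    edge_times <- function(a, b) {
      lvl <- max(thr, 0.5 * max(s[a:b]))
      a2 <- min(which(s[a:b] >= lvl)) + a - 1L
      b2 <- max(which(s[a:b] >= lvl)) + a - 1L
      rise <- if (a2 > 1 && s[a2 - 1] < lvl) {
        (a2 - 1 + (lvl - s[a2 - 1]) / (s[a2] - s[a2 - 1]) - 1) * dt
      } else (a2 - 1) * dt
      fall <- if (b2 < length(s) && s[b2 + 1] < lvl) {
        (b2 + (lvl - s[b2]) / (s[b2 + 1] - s[b2]) - 1) * dt
      } else (b2 - 1) * dt
      c(rise, fall)
    }
    if (length(ep) < 2) {
      sp <- if (length(ep) == 1) {
        et <- edge_times(starts[ep], ends[ep])
        et[2] - et[1]
      } else NA_real_
      return(c(sp = sp, iso = NA, lp = NA, thr = thr, flagged = 1))
    }
    first <- ep[1]; last <- ep[length(ep)]
    e_sp <- edge_times(starts[first], ends[first])
    e_lp <- edge_times(starts[last], ends[last])
    sp <- e_sp[2] - e_sp[1]
    lp <- e_lp[2] - e_lp[1]
    iso <- e_lp[1] - e_sp[2]
    c(sp = sp, iso = iso, lp = lp, thr = thr, flagged = 0)
  })
  m <- as.data.frame(do.call(rbind, out))
  res <- data.frame(sp = m$sp, iso = m$iso, lp = m$lp)
  res$shortening_velocity <- ifelse(
    is.finite(m$sp) & m$sp > 0, (bt$dd - bt$sd) / m$sp, NA_real_)
  res$threshold_um_s <- m$thr
  res$flagged <- m$flagged > 0
  class(res) <- c("phase_table", "data.frame")
  res
}

#' Shortening velocity
#'
#' Shortening velocity of one contraction: the wall travel distance
#' divided by the shortening-phase duration,
#' `(diastolic diameter - systolic diameter) / SP`.
#'
#' @param dd Diastolic diameter, um.
#' @param sd Systolic diameter, um.
#' @param sp Shortening-phase duration, s.
#' @return Velocity in um/s.
#' @examples
#' shortening_velocity(80, 60, 0.1)  # 200 um/s
#' @export
shortening_velocity <- function(dd, sd, sp) {
  if (any(sp <= 0)) stop("SP must be > 0", call. = FALSE)
  if (any(dd < sd)) stop("DD must be >= SD", call. = FALSE)
  (dd - sd) / sp
}

#' Pre/Load/Post viscous-load protocol report
#'
#' Summarizes the three-condition load protocol (baseline hemolymph,
#' 20% Ficoll load, recovery) per heart: mean isometric duration and mean
#' shortening velocity in each condition, the load contrast
#' (Load - Pre), and a recovery check (Post close to Pre).
#'
#' @param pre,load,post Named lists of `phase_table`s keyed by heart ID
#'   (IDs must match across conditions).
#' @param recovery_tol Relative tolerance on mean ISO for the per-heart
#'   recovery flag (default 0.25); an absolute floor of 2 frame periods at
#'   200 fps (0.01 s) is also applied.
#' @return A `load_report`: list with `per_heart` (data.frame of per-heart
#'   condition means and contrasts) and `summary` (cohort means, recovery
#'   fraction).
#' @export
load_protocol_report <- function(pre, load, post, recovery_tol = 0.25) {
  for (x in list(pre, load, post)) {
    if (is.null(names(x))) {
      stop("conditions must be named lists keyed by heart ID", call. = FALSE)
    }
  }
  ids <- names(pre)
  missing <- c(setdiff(ids, names(load)), setdiff(ids, names(post)),
               setdiff(names(load), ids), setdiff(names(post), ids))
  if (length(missing)) {
    stop("heart IDs missing from a condition: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  mfin <- function(x) mean(x[is.finite(x)])
  per <- do.call(rbind, lapply(ids, function(id) {
    data.frame(
      heart = id,
      iso_pre = mfin(pre[[id]]$iso),
      iso_load = mfin(load[[id]]$iso),
      iso_post = mfin(post[[id]]$iso),
      vel_pre = mfin(pre[[id]]$shortening_velocity),
      vel_load = mfin(load[[id]]$shortening_velocity),
      vel_post = mfin(post[[id]]$shortening_velocity))
  }))
  per$delta_iso_load <- per$iso_load - per$iso_pre
  per$delta_iso_post <- per$iso_post - per$iso_pre
  tol <- pmax(recovery_tol * abs(per$iso_pre), 0.01)
  per$recovered <- abs(per$delta_iso_post) <= tol
  structure(list(
    per_heart = per,
    summary = list(
      mean_iso_pre = mean(per$iso_pre),
      mean_iso_load = mean(per$iso_load),
      mean_iso_post = mean(per$iso_post),
      mean_delta_iso_load = mean(per$delta_iso_load),
      mean_vel_pre = mean(per$vel_pre),
      mean_vel_load = mean(per$vel_load),
      recovery_fraction = mean(per$recovered))
  ), class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<load_report> %d hearts | ISO pre %.3g s -> load %.3g s -> post %.3g s\n",
              nrow(x$per_heart), s$mean_iso_pre, s$mean_iso_load,
              s$mean_iso_post))
  cat(sprintf("  load contrast %.3g s; recovered: %.0f%% of hearts\n",
              s$mean_delta_iso_load, 100 * s$recovery_fraction))
  invisible(x)
}
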