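# TTL-based alignment of simultaneous optical and electrical recordings,
# and AP-to-contraction event matching.

#' Locate the TTL pulse window
#'
#' The image-capture software raises a TTL pulse for the entire optical
#' recording; this finds the half-open window `[first rise, last fall)` of
#' the auxiliary channel at half amplitude. Exactly one contiguous pulse
#' is required.
#'
#' @param trace A [voltage_trace()] with an `aux` channel.
#' @return Numeric `c(on, off)` in seconds (electrical clock).
#' @export
locate_ttl <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  aux <- trace$aux
  if (is.null(aux)) stop("voltage trace has no auxiliary (TTL) channel",
                         call. = FALSE)
  lo <- min(aux); hi <- max(aux)
  if (hi - lo < 1e-6) stop("TTL channel carries no pulse", call. = FALSE)
  high <- aux > (lo + hi) / 2
  r <- rle(high)
  if (sum(r$values) != 1L) {
    stop(sum(r$values), " disjoint TTL pulses found (expected exactly 1)",
         call. = FALSE)
  }
  i1 <- which(high)[1]
  i2 <- max(which(high))
  dt <- 1 / trace$rate
  c(trace$t[i1], trace$t[i2] + dt)
}

#' Align an optical recording to the electrical clock
#'
#' Optical frame j (0-based) is assigned electrical time
#' `t_on + j / fps`, where `t_on` is the TTL rise.
#'
#' @param voltage A [voltage_trace()] with a TTL aux channel.
#' @param optical A [diameter_trace()] (or [mmode_image()]) covering the
#'   TTL window.
#' @param max_skew_frames Maximum tolerated mismatch between optical
#'   duration and TTL window length, in frames (default 2).
#' @return A `sync_pair` with the optical trace re-timed onto the
#'   electrical clock.
#' @export
align_pair <- function(voltage, optical, max_skew_frames = 2) {
  win <- locate_ttl(voltage)
  fps <- optical$fps
  nfr <- if (inherits(optical, "mmode_image")) ncol(optical$pixels) else
    length(optical$t)
  skew <- abs(nfr / fps - (win[2] - win[1]))
  if (skew > max_skew_frames / fps) {
    stop(sprintf(
      "optical duration (%.4g s) does not match TTL window (%.4g s)",
      nfr / fps, win[2] - win[1]), call. = FALSE)
  }
  if (inherits(optical, "diameter_trace")) {
    optical$t <- win[1] + (seq_len(nfr) - 1) / fps
  }
  structure(list(voltage = voltage, optical = optical,
                 offset = win[1], window = win),
            class = "sync_pair")
}

#' Match AP events to heart contractions
#'
#' Greedy nearest-neighbor matching of AP-event onsets to contraction
#' onsets within a tolerance, each event used at most once (candidate
#' pairs are processed in order of absolute latency, so the result is
#' symmetric in which table is the query).
#'
#' @param beats A `beat_table` (onsets on the aligned/electrical clock).
#' @param aps An `ap_event_table` (onsets on the same clock).
#' @param tolerance_s Maximum |AP onset - contraction onset| for a match,
#'   seconds (default 0.15).
#' @return A `match_report`: list with `n_beats`, `n_ap_events`,
#'   `n_matched`, `matched_fraction` (share of contractions matched),
#'   `median_latency_s` (AP onset minus contraction onset), and `pairs`
#'   (data.frame of matched index pairs and latencies).
#' @export
match_events <- function(beats, aps, tolerance_s = 0.15) {
  if (tolerance_s <= 0) stop("tolerance must be > 0", call. = FALSE)
  bo <- beats$onset
  ao <- aps$onset
  nb <- length(bo); na_ <- length(ao)
  pairs <- data.frame(beat = integer(0), ap = integer(0),
                      latency = numeric(0))
  if (nb && na_) {
    cand <- expand.grid(beat = seq_len(nb), ap = seq_len(na_))
    cand$latency <- ao[cand$ap] - bo[cand$beat]
    cand <- cand[abs(cand$latency) <= tolerance_s, , drop = FALSE]
    cand <- cand[order(abs(cand$latency), cand$beat, cand$ap), ,
                 drop = FALSE]
    used_b <- logical(nb); used_a <- logical(na_)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      b <- cand$beat[i]; a <- cand$ap[i]
      if (!used_b[b] && !used_a[a]) {
        keep[i] <- TRUE; used_b[b] <- TRUE; used_a[a] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  structure(list(
    n_beats = nb, n_ap_events = na_, n_matched = nrow(pairs),
    matched_fraction = if (nb) nrow(pairs) / nb else 0,
    median_latency_s = if (nrow(pairs)) stats::median(pairs$latency)
    else NA_real_,
    pairs = pairs
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> %d/%d contractions matched to %d AP events (%.1f%%), median latency %s\n",
    x$n_matched, x$n_beats, x$n_ap_events, 100 * x$matched_fraction,
    if (is.na(x$median_latency_s)) "NA"
    else sprintf("%.1f ms", 1000 * x$median_latency_s)))
  invisible(x)
}
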