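#' Diameter trace container
#'
#' A uniformly sampled inner-diameter time series — the common currency
#' between the imaging and beat-analysis stages.
#'
#' @param t Time in seconds (uniform grid).
#' @param d Inner diameter in micrometers.
#' @param fps Sampling rate, frames per second.
#' @param provenance Free-text origin tag (e.g. `"synthetic"` or a movie
#'   line description).
#' @return A `diameter_trace` object.
#' @export
diameter_trace <- function(t, d, fps, provenance = "unknown") {
  stopifnot(length(t) == length(d), fps > 0, all(is.finite(d)))
  structure(list(t = as.numeric(t), d = as.numeric(d), fps = fps,
                 provenance = provenance),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("<diameter_trace> %d samples @ %g fps (%.3g s), d in [%.4g, %.4g] um [%s]\n",
              length(x$t), x$fps, length(x$t) / x$fps,
              min(x$d), max(x$d), x$provenance))
  invisible(x)
}

#' Voltage trace container
#'
#' @param t Time in seconds (uniform grid).
#' @param v Membrane potential, mV.
#' @param rate Sampling rate, samples per second.
#' @param aux Optional auxiliary (TTL) channel, same length as `v`.
#' @return A `voltage_trace` object.
#' @export
voltage_trace <- function(t, v, rate, aux = NULL) {
  stopifnot(length(t) == length(v), rate > 0, all(is.finite(v)))
  if (!is.null(aux)) stopifnot(length(aux) == length(v))
  structure(list(t = as.numeric(t), v = as.numeric(v), rate = rate,
                 aux = if (is.null(aux)) NULL else as.numeric(aux)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.3g s), v in [%.4g, %.4g] mV%s\n",
              length(x$t), x$rate, length(x$t) / x$rate,
              min(x$v), max(x$v),
              if (is.null(x$aux)) "" else " + TTL aux"))
  invisible(x)
}

#' Frame stack container
#'
#' @param frames Numeric 3-D array `[rows, cols, frames]` of grayscale
#'   intensities.
#' @param fps Frame rate, frames per second.
#' @param scale Spatial calibration, micrometers per pixel.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, scale) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, fps > 0, scale > 0)
  structure(list(frames = frames, fps = fps, scale = scale),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g fps, %.3g um/px\n",
              d[3], d[1], d[2], x$fps, x$scale))
  invisible(x)
}

#' M-mode kymograph container
#'
#' @param pixels Space-by-time intensity matrix (one column per frame).
#' @param line Sampling segment `c(x1, y1, x2, y2)` in 0-based pixel-center
#'   frame coordinates.
#' @param fps Frame rate, frames per second.
#' @param scale Micrometers per pixel along the sampling line.
#' @return An `mmode_image` object.
#' @export
mmode_image <- function(pixels, line, fps, scale) {
  stopifnot(is.matrix(pixels), length(line) == 4, fps > 0, scale > 0)
  structure(list(pixels = pixels, line = as.numeric(line),
                 fps = fps, scale = scale),
            class = "mmode_image")
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf("<mmode_image> %d px x %d frames @ %g fps, %.3g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$fps, x$scale))
  invisible(x)
}
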