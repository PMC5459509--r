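# M-mode kymograph extraction and heart-wall tracking.
#
# Coordinate conventions: 0-based pixel centers, 0-based time index,
# half-open intervals [start, end).

#' Extract an M-mode kymograph from a movie
#'
#' Samples intensity along a fixed line segment (transverse to the tube
#' axis) in every frame; column j of the output is the bilinear intensity
#' sample along the line in frame j.
#'
#' @param stack A [frame_stack()].
#' @param line Numeric `c(x1, y1, x2, y2)` in 0-based pixel-center
#'   coordinates (x = column, y = row).
#' @return An [mmode_image()]; the pixel pitch along the line equals the
#'   frame pixel pitch (samples are spaced 1 px apart along the segment).
#' @export
extract_mmode <- function(stack, line) {
  stopifnot(inherits(stack, "frame_stack"), length(line) == 4)
  d <- dim(stack$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]
  x1 <- line[1]; y1 <- line[2]; x2 <- line[3]; y2 <- line[4]
  if (any(c(x1, x2) < 0) || any(c(x1, x2) > w - 1) ||
      any(c(y1, y2) < 0) || any(c(y1, y2) > h - 1)) {
    stop("sampling line lies outside the frame bounds", call. = FALSE)
  }
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ns <- max(2L, as.integer(floor(len)) + 1L)
  fr <- seq(0, 1, length.out = ns)
  xs <- x1 + fr * (x2 - x1)
  ys <- y1 + fr * (y2 - y1)

  # bilinear weights, shared across frames
  x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- (x0) * h + y0 + 1          # column-major linear index, frame 0
  w00 <- (1 - fx) * (1 - fy)
  w01 <- fx * (1 - fy)              # (x0+1, y0)
  w10 <- (1 - fx) * fy              # (x0, y0+1)
  w11 <- fx * fy
  px <- matrix(0, ns, nt)
  fsz <- h * w
  f <- stack$frames
  for (j in seq_len(nt)) {
    base <- (j - 1) * fsz
    px[, j] <- w00 * f[base + i00] + w01 * f[base + i00 + h] +
      w10 * f[base + i00 + 1] + w11 * f[base + i00 + h + 1]
  }
  mmode_image(px, line, stack$fps, stack$scale)
}

# running mean with edge replication; k forced odd
.runmean <- function(x, k) {
  if (k <= 1) return(x)
  k <- as.integer(k); if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- cumsum(xp)
  (cs[(k):(n + k - 1L)] - c(0, cs[1:(n - 1L)])) / k
}

# sub-pixel edge position: intensity-weighted centroid of the gradient
# lobe around the discrete extremum at idx[k] (exact for a symmetrically
# blurred step edge)
.grad_centroid <- function(g, idx, k) {
  gk <- g[idx[k]]
  lo <- k; hi <- k
  while (lo > 1 && g[idx[lo - 1]] > 0.3 * gk) lo <- lo - 1
  while (hi < length(idx) && g[idx[hi + 1]] > 0.3 * gk) hi <- hi + 1
  win <- idx[lo:hi]
  w <- pmax(g[win], 0)
  sum(win * w) / sum(w)
}

# locate the two wall bands and their inner edges in one smoothed column
# profile; returns diameter in px or NA
.track_column <- function(p) {
  rng <- diff(range(p))
  if (rng < 1e-6) return(NA_real_)
  thr <- min(p) + 0.5 * rng
  below <- p < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bands <- which(r$values)
  if (length(bands) < 2) return(NA_real_)
  # two deepest bands
  depth <- vapply(bands, function(b) min(p[starts[b]:ends[b]]), 0)
  sel <- bands[order(depth)[1:2]]
  sel <- sel[order(starts[sel])]
  ctr_up <- {
    i <- starts[sel[1]]:ends[sel[1]]
    i[which.min(p[i])]
  }
  ctr_lo <- {
    i <- starts[sel[2]]:ends[sel[2]]
    i[which.min(p[i])]
  }
  if (ctr_lo - ctr_up < 3) return(NA_real_)
  mid <- (ends[sel[1]] + starts[sel[2]]) / 2   # middle of the lumen gap
  g <- c(0, (p[3:length(p)] - p[1:(length(p) - 2)]) / 2, 0)  # central diff
  # upper inner edge: strongest rising gradient between band center and lumen
  iu <- ctr_up:floor(mid)
  edge_up <- .grad_centroid(g, iu, which.max(g[iu]))
  # lower inner edge: strongest falling gradient between lumen and band center
  il <- ceiling(mid):ctr_lo
  edge_lo <- .grad_centroid(-g, il, which.min(g[il]))
  if (edge_lo <= edge_up) return(NA_real_)
  edge_lo - edge_up
}

#' Track the heart walls in an M-mode kymograph
#'
#' Per column, the two wall bands are located as the two deepest
#' below-midlevel intensity runs; the inner edge of each band is the
#' extremum of the smoothed intensity gradient on the lumen side, refined
#' to sub-pixel precision by quadratic interpolation. Diameter = inner
#' edge separation times the spatial scale. Columns failing detection are
#' linearly interpolated and flagged; more than `max_fail` failed columns
#' aborts with a diagnostic.
#'
#' The result is invariant to global intensity scaling and to vertical
#' reflection of the frames (all thresholds are relative to the per-column
#' intensity range).
#'
#' @param mm An [mmode_image()].
#' @param smooth_px Column smoothing window in pixels (running mean,
#'   default 5).
#' @param max_fail Maximum tolerated fraction of failed columns
#'   (default 0.1).
#' @return A [diameter_trace()]; attribute `failed_columns` lists the
#'   (1-based) interpolated column indices.
#' @export
track_walls <- function(mm, smooth_px = 5, max_fail = 0.1) {
  stopifnot(inherits(mm, "mmode_image"))
  nt <- ncol(mm$pixels)
  d_px <- numeric(nt)
  for (j in seq_len(nt)) {
    p <- .runmean(mm$pixels[, j], smooth_px)
    d_px[j] <- .track_column(p)
  }
  failed <- which(is.na(d_px))
  if (length(failed) == nt) {
    stop("wall tracking failed in every column: no wall bands detected",
         call. = FALSE)
  }
  if (length(failed) / nt > max_fail) {
    stop(sprintf(
      "wall tracking failed in %d/%d columns (%.1f%% > %.1f%% allowed)",
      length(failed), nt, 100 * length(failed) / nt, 100 * max_fail),
      call. = FALSE)
  }
  if (length(failed)) {
    ok <- which(!is.na(d_px))
    d_px[failed] <- stats::approx(ok, d_px[ok], xout = failed,
                                  rule = 2)$y
  }
  t <- (seq_len(nt) - 1) / mm$fps
  out <- diameter_trace(t, d_px * mm$scale, mm$fps,
                        provenance = sprintf("mmode line %s",
                                             paste(mm$line, collapse = ",")))
  attr(out, "failed_columns") <- failed
  out
}
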