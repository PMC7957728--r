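#' Dynamic acquisition protocol
#'
#' An acquisition protocol is the frame schedule of a dynamic PET study:
#' frame start times and frame durations in seconds. Frames must be
#' contiguous (each frame starts where the previous one ends) so that the
#' schedule tiles the acquisition window without gaps.
#'
#' @param frame_starts Numeric vector of frame start times in seconds,
#'   non-negative and strictly increasing.
#' @param frame_durations Numeric vector of frame durations in seconds,
#'   strictly positive, same length as `frame_starts`.
#'
#' @return An object of class `acquisition_protocol`: a list with elements
#'   `frame_starts`, `frame_durations` (seconds) and `n_frames`.
#'
#' @examples
#' p <- default_protocol()
#' p$n_frames                      # 24
#' sum(p$frame_durations)          # 3600 s = 60 min
#' @export
acquisition_protocol <- function(frame_starts, frame_durations) {
  frame_starts <- as.numeric(frame_starts)
  frame_durations <- as.numeric(frame_durations)
  if (length(frame_starts) == 0L || length(frame_starts) != length(frame_durations))
    stop("frame_starts and frame_durations must be non-empty and equal length")
  if (any(!is.finite(frame_starts)) || any(!is.finite(frame_durations)))
    stop("frame schedule must be finite")
  if (frame_starts[1] < 0) stop("frame_starts must be non-negative")
  if (any(frame_durations <= 0)) stop("frame_durations must be positive")
  if (length(frame_starts) > 1L) {
    if (any(diff(frame_starts) <= 0)) stop("frame_starts must be strictly increasing")
    gaps <- frame_starts[-1] - (frame_starts[-length(frame_starts)] +
                                  frame_durations[-length(frame_durations)])
    if (any(abs(gaps) > 1e-9))
      stop("frames must be contiguous: start[i+1] = start[i] + duration[i]")
  }
  structure(
    list(frame_starts = frame_starts,
         frame_durations = frame_durations,
         n_frames = length(frame_starts)),
    class = "acquisition_protocol"
  )
}

#' Default 24-frame / 60-minute dynamic protocol
#'
#' The standard dynamic FDG schedule used throughout: 10 frames of 30 s,
#' 5 frames of 60 s, 5 frames of 120 s and 4 frames of 600 s, totalling
#' 3600 s.
#'
#' @return An [acquisition_protocol()].
#' @export
default_protocol <- function() {
  durations <- c(rep(30, 10), rep(60, 5), rep(120, 5), rep(600, 4))
  acquisition_protocol(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Frame mid-times in minutes
#'
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of frame midpoints, in minutes.
#' @export
frame_mid_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  (protocol$frame_starts + protocol$frame_durations / 2) / 60
}

#' Tissue time-activity curve
#'
#' A frame-averaged activity-concentration curve (kBq/mL) on a given
#' acquisition protocol, together with per-frame non-negative fit weights.
#' Default weights are proportional to frame duration, a standard proxy for
#' relative count statistics.
#'
#' @param protocol An [acquisition_protocol()].
#' @param values Numeric vector of frame-averaged activity concentrations
#'   (kBq/mL), one per frame.
#' @param weights Optional numeric vector of non-negative fit weights, one
#'   per frame; defaults to the frame durations.
#'
#' @return An object of class `tissue_tac`.
#' @export
tissue_tac <- function(protocol, values, weights = NULL) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  values <- as.numeric(values)
  if (length(values) != protocol$n_frames)
    stop("values length must equal the number of frames")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (is.null(weights)) weights <- protocol$frame_durations
  weights <- as.numeric(weights)
  if (length(weights) != protocol$n_frames || any(weights < 0) ||
      any(!is.finite(weights)))
    stop("weights must be non-negative, finite, one per frame")
  structure(list(protocol = protocol, values = values, weights = weights),
            class = "tissue_tac")
}

#' Average a continuous curve over the frames of a protocol
#'
#' Maps a continuous concentration curve to the frame schedule: the value of
#' frame f is the mean of the curve over `[start_f, start_f + duration_f)`.
#' The mean is computed by uniform sub-sampling at `dt` resolution
#' (midpoint-offset), which is exact for curves linear within a frame.
#'
#' @param curve A function of time in minutes returning concentration, or a
#'   list/data.frame with `time` (minutes) and `value` to be linearly
#'   interpolated.
#' @param protocol An [acquisition_protocol()].
#' @param dt Sub-sampling resolution in seconds (default 1).
#'
#' @return A [tissue_tac()] with duration weights.
#' @export
frame_average <- function(curve, protocol, dt = 1) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  f <- as_curve_function(curve)
  end_s <- protocol$frame_starts[protocol$n_frames] +
    protocol$frame_durations[protocol$n_frames]
  vals <- vapply(seq_len(protocol$n_frames), function(i) {
    s <- protocol$frame_starts[i]
    d <- protocol$frame_durations[i]
    n <- max(1L, ceiling(d / dt))
    # midpoint rule on n uniform sub-intervals: exact for linear curves
    tt <- s + (seq_len(n) - 0.5) * (d / n)
    mean(f(tt / 60))
  }, numeric(1))
  if (any(!is.finite(vals)))
    stop("curve is not defined over the full protocol window [0, ",
         end_s, "] s")
  tissue_tac(protocol, vals)
}

# Coerce a curve specification to a function of time in minutes.
as_curve_function <- function(curve) {
  if (is.function(curve)) return(curve)
  if (is.list(curve) && !is.null(curve$time) && !is.null(curve$value)) {
    time <- as.numeric(curve$time); value <- as.numeric(curve$value)
    return(function(t) stats::approx(time, value, xout = t, rule = 1)$y)
  }
  stop("curve must be a function(t_minutes) or a list with $time and $value")
}
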