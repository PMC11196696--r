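#' Min-max normalize and detrend a trace
#'
#' Rescales the amplitudes to \[0, 1\] (min-max) and then subtracts the
#' mean of the scaled signal, so the output has zero mean and unit
#' peak-to-peak range. Normalizing before detrending makes the
#' percentile-based peak threshold downstream comparable across sensors
#' of different gains, and renders the whole pipeline invariant to
#' positive affine transforms of the raw amplitudes.
#'
#' @param trace A [seismic_trace()] with at least 2 samples.
#' @return A [seismic_trace()] with transformed samples.
#' @details A constant trace has no range to normalize; it is mapped to
#'   all zeros with a warning.
#' @examples
#' tr <- seismic_trace(c(0, 5, 10), fs = 100)
#' detrend_normalize(tr)$samples  # -0.5 0.0 0.5
#' @export
detrend_normalize <- function(trace) {
  stopifnot(inherits(trace, "seismic_trace"))
  x <- trace$samples
  if (length(x) < 2L) stop("need at least 2 samples")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("constant trace: normalized to all zeros")
    y <- rep(0, length(x))
  } else {
    y <- (x - rng[1L]) / (rng[2L] - rng[1L])
    y <- y - mean(y)
  }
  trace$samples <- y
  trace
}

#' Temporally align traces onto a common grid
#'
#' Resamples every trace by linear interpolation onto the grid of the
#' nominal sampling rate (the median of the traces' rates) over the
#' intersection of their time ranges. Footstep transients at 100 Hz leave
#' no headroom for band-limited reconstruction, and inter-sensor clock
#' offsets are sub-sample, so linear interpolation is adequate.
#'
#' @param traces List of [seismic_trace()] with overlapping time ranges
#'   and sampling rates within 1% of each other.
#' @return List of [seismic_trace()] sharing `t0`, `fs` and length.
#' @export
align_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  lapply(traces, function(tr) stopifnot(inherits(tr, "seismic_trace")))
  fss <- vapply(traces, `[[`, 0, "fs")
  fs <- stats::median(fss)
  if (any(abs(fss - fs) > 0.01 * fs))
    stop("sampling rates differ by more than 1%; cannot align")
  starts <- vapply(traces, `[[`, 0, "t0")
  ends <- vapply(traces, function(tr) max(trace_times(tr)), 0)
  lo <- max(starts); hi <- min(ends)
  if (hi <= lo) stop("traces have no temporal overlap")
  grid <- seq(lo, hi, by = 1 / fs)
  lapply(traces, function(tr) {
    y <- stats::approx(trace_times(tr), tr$samples, xout = grid,
                       method = "linear", rule = 2)$y
    seismic_trace(y, fs = fs, t0 = lo, sensor_id = tr$sensor_id,
                  position = tr$position)
  })
}

#' Aggregate aligned traces by a rolling maximum
#'
#' Combines the sensors into one composite signal: for each grid time
#' `t_i` the output is the maximum over all sensors and all samples within
#' `window / 2` seconds of `t_i`. With `window = 0` this is the pointwise
#' maximum across sensors. Taking the maximum counteracts per-sensor
#' amplitude damping (the sensor closest to a footstep dominates) and,
#' with a window spanning at least one period of the footstep transient's
#' dominant frequency, turns the oscillatory transient into its upper
#' envelope.
#'
#' @param traces List of aligned, equal-length [seismic_trace()].
#' @param window Rolling window width in seconds (default 0.08; `>= 0`).
#' @return A [seismic_trace()] holding the composite signal (sensor id
#'   `"agg"`).
#' @export
aggregate_max <- function(traces, window = 0.08) {
  if (length(traces) == 0L) stop("empty trace list")
  lapply(traces, function(tr) stopifnot(inherits(tr, "seismic_trace")))
  if (window < 0) stop("'window' must be >= 0")
  n <- lengths(lapply(traces, `[[`, "samples"))
  if (length(unique(n)) != 1L)
    stop("traces must be aligned to equal length; use align_traces()")
  fs <- traces[[1L]]$fs
  m <- do.call(pmax, lapply(traces, `[[`, "samples"))
  half <- floor(window / 2 * fs + 1e-9)
  if (half > 0L)
    m <- mm_dilate(m, rep(0, 2L * half + 1L))  # flat dilation = rolling max
  seismic_trace(m, fs = fs, t0 = traces[[1L]]$t0, sensor_id = "agg")
}
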