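#' Seismic trace
#'
#' A single sensor's evenly sampled floor-vibration record. Times are
#' recording-relative seconds: sample `k` (1-based) lies at
#' `t0 + (k - 1) / fs`. Amplitudes are in arbitrary sensor units and are
#' never interpreted physically; the detection pipeline is invariant to
#' positive rescaling.
#'
#' @param samples Numeric vector of amplitudes (non-empty).
#' @param fs Sampling rate in Hz (nominal 100 for the supported geophones).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param sensor_id Character label for the sensor.
#' @param position Optional numeric `c(x, y)` position in metres along /
#'   across the walkway.
#'
#' @return An object of class `seismic_trace`: a list with fields
#'   `sensor_id`, `t0`, `fs`, `samples`, `position`.
#' @examples
#' tr <- seismic_trace(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' trace_times(tr)[1:3]
#' @export
seismic_trace <- function(samples, fs, t0 = 0, sensor_id = "s1",
                          position = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 2L) stop("'position' must be c(x, y) in metres")
  }
  structure(
    list(sensor_id = as.character(sensor_id), t0 = as.numeric(t0),
         fs = fs, samples = samples, position = position),
    class = "seismic_trace"
  )
}

#' @export
print.seismic_trace <- function(x, ...) {
  cat(sprintf("<seismic_trace> sensor %s: %d samples @ %g Hz, t0 = %g s\n",
              x$sensor_id, length(x$samples), x$fs, x$t0))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [seismic_trace()].
#' @return Numeric vector of times in seconds, `t0 + (k - 1) / fs`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "seismic_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' Walk metadata
#'
#' Descriptive metadata for one recorded walk: the identifier, the active
#' walkway length used for the spatial parameter approximations, which foot
#' struck first, and the experiment type.
#'
#' @param walk_id Character walk identifier.
#' @param walkway_length_cm Active walkway length in centimetres
#'   (default 488, a standard pressure-sensitive walkway).
#' @param first_foot `"left"`, `"right"` or `"unknown"`.
#' @param experiment One of `"free"`, `"fast"`, `"normal"`, `"tug"`.
#' @return An object of class `walk_metadata`.
#' @export
walk_metadata <- function(walk_id = "walk", walkway_length_cm = 488,
                          first_foot = c("unknown", "left", "right"),
                          experiment = c("free", "fast", "normal", "tug")) {
  first_foot <- match.arg(first_foot)
  experiment <- match.arg(experiment)
  if (!is.numeric(walkway_length_cm) || walkway_length_cm <= 0)
    stop("'walkway_length_cm' must be positive")
  structure(
    list(walk_id = as.character(walk_id),
         walkway_length_cm = as.numeric(walkway_length_cm),
         first_foot = first_foot, experiment = experiment),
    class = "walk_metadata"
  )
}

#' Footstep events
#'
#' Ordered initial-contact timestamps extracted from a walk, with optional
#' per-event foot labels. Construction enforces strictly increasing times;
#' the detector additionally guarantees a minimum inter-event distance.
#'
#' @param times Strictly increasing numeric vector of event times (s).
#' @param feet Optional character vector (`"left"`/`"right"`/`NA`), one per
#'   event.
#' @param source Walk identifier the events came from.
#' @return An object of class `footstep_events`.
#' @export
footstep_events <- function(times, feet = NULL, source = "walk") {
  times <- as.numeric(times)
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  if (!is.null(feet)) {
    feet <- as.character(feet)
    if (length(feet) != length(times))
      stop("'feet' must have one label per event")
  }
  structure(list(times = times, feet = feet, source = as.character(source)),
            class = "footstep_events")
}

#' @export
print.footstep_events <- function(x, ...) {
  cat(sprintf("<footstep_events> %d events from '%s'\n",
              length(x$times), x$source))
  if (length(x$times)) {
    lab <- if (is.null(x$feet)) rep("?", length(x$times)) else x$feet
    cat(paste(sprintf("  %7.3f s  %s", x$times, lab), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.footstep_events <- function(x) length(x$times)
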