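#' Assign alternating foot labels
#'
#' Footedness is not detectable from the vibration signal; the first
#' foot is supplied externally (in the validation study it came from the
#' camera recording) and subsequent events alternate strictly. With an
#' unknown first foot the labels are left unset; all gait arithmetic
#' uses event order only, so labels are purely presentational.
#'
#' @param events A [footstep_events()] object with >= 1 event.
#' @param first_foot `"left"`, `"right"` or `"unknown"`.
#' @return The events with `feet` filled in (or `NULL` if unknown).
#' @export
assign_feet <- function(events, first_foot = c("unknown", "left", "right")) {
  stopifnot(inherits(events, "footstep_events"))
  first_foot <- match.arg(first_foot)
  n <- length(events$times)
  if (first_foot == "unknown") {
    events$feet <- NULL
    return(events)
  }
  if (n == 0L) stop("no events to label")
  pair <- if (first_foot == "left") c("left", "right") else c("right", "left")
  events$feet <- rep_len(pair, n)
  events
}

#' Compute spatiotemporal gait parameters from footstep events
#'
#' With ordered initial-contact times `t_1 < ... < t_n` and successive
#' intervals `d_i = t_(i+1) - t_i`:
#' * step time (s): `mean(d_i)` — average interval between contralateral
#'   initial contacts;
#' * cycle time (s): `mean(t_(i+2) - t_i)` — average interval between
#'   ipsilateral contacts (about two step times);
#' * ambulation time (s): `sum(d_i) = t_n - t_1` — the sum of step times;
#' * cadence (steps/min): `60 * n / ambulation_time` — the ratio of the
#'   number of identified steps to the ambulation time;
#' * velocity (cm/s): `walkway_length / ambulation_time` (approximated
#'   via the known walkway length);
#' * step length (cm): `mean(velocity * d_i) = velocity * step_time`
#'   (approximated).
#'
#' The temporal parameters are exact functions of the event timestamps;
#' velocity and step length are approximations that assume the walk
#' spans the active walkway length.
#'
#' @param events A [footstep_events()] with >= 2 events (>= 3 for cycle
#'   time).
#' @param meta A [walk_metadata()] (supplies the walkway length), or a
#'   single numeric walkway length in cm.
#' @return Object of class `gait_parameters` with fields `step_time`,
#'   `cycle_time`, `ambulation_time`, `cadence`, `velocity`,
#'   `step_length`, `n_steps`, `walkway_length_cm`. With exactly 2
#'   events, `cycle_time` and `step_length` are `NA`.
#' @examples
#' ev <- footstep_events(c(0, 0.6, 1.2, 1.8, 2.4))
#' compute_gait_parameters(ev, 488)
#' @export
compute_gait_parameters <- function(events, meta = walk_metadata()) {
  stopifnot(inherits(events, "footstep_events"))
  if (is.numeric(meta)) meta <- walk_metadata(walkway_length_cm = meta)
  stopifnot(inherits(meta, "walk_metadata"))
  t <- events$times
  n <- length(t)
  if (n < 2L) stop("insufficient events: need at least 2 footsteps")
  d <- diff(t)
  step_time <- mean(d)
  ambulation_time <- sum(d)
  cadence <- 60 * n / ambulation_time
  velocity <- meta$walkway_length_cm / ambulation_time
  if (n >= 3L) {
    cycle_time <- mean(t[seq.int(3L, n)] - t[seq.int(1L, n - 2L)])
    step_length <- mean(velocity * d)  # = velocity * step_time
  } else {
    cycle_time <- NA_real_
    step_length <- NA_real_
  }
  structure(
    list(step_time = step_time, cycle_time = cycle_time,
         ambulation_time = ambulation_time, cadence = cadence,
         velocity = velocity, step_length = step_length, n_steps = n,
         walkway_length_cm = meta$walkway_length_cm),
    class = "gait_parameters"
  )
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat("<gait_parameters>\n")
  cat(sprintf("  step time        %8.3f s\n", x$step_time))
  cat(sprintf("  cycle time       %8.3f s\n", x$cycle_time))
  cat(sprintf("  ambulation time  %8.3f s\n", x$ambulation_time))
  cat(sprintf("  cadence          %8.2f steps/min\n", x$cadence))
  cat(sprintf("  velocity         %8.2f cm/s\n", x$velocity))
  cat(sprintf("  step length      %8.2f cm\n", x$step_length))
  cat(sprintf("  steps            %8d\n", x$n_steps))
  invisible(x)
}

#' @export
as.data.frame.gait_parameters <- function(x, ...) {
  data.frame(step_time = x$step_time, cycle_time = x$cycle_time,
             ambulation_time = x$ambulation_time, cadence = x$cadence,
             velocity = x$velocity, step_length = x$step_length,
             n_steps = x$n_steps)
}

#' Timed up-and-go (TUG) timing from footstep events
#'
#' In a TUG recording the initial peak of the seismic signal marks the
#' start of the test (rising from the chair) and the last peak the end
#' (sitting back down), so the test duration is the span of the detected
#' events.
#'
#' @param events A [footstep_events()] with >= 2 events.
#' @return Object of class `tug_timing` with `start`, `end`, `duration`
#'   in seconds.
#' @examples
#' compute_tug(footstep_events(c(2.0, 3.1, 4.4, 10.3)))$duration  # 8.3
#' @export
compute_tug <- function(events) {
  stopifnot(inherits(events, "footstep_events"))
  t <- events$times
  if (length(t) < 2L) stop("insufficient events: need at least 2 peaks")
  structure(list(start = t[1L], end = t[length(t)],
                 duration = t[length(t)] - t[1L]),
            class = "tug_timing")
}

#' @export
print.tug_timing <- function(x, ...) {
  cat(sprintf("<tug_timing> start %.3f s, end %.3f s, duration %.3f s\n",
              x$start, x$end, x$duration))
  invisible(x)
}
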