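#' Read vibration traces from a CSV file
#'
#' Two dialects are supported. Long form: header `time,amplitude`, one file
#' per sensor. Wide form: header `time,s1,s2,...`, one amplitude column per
#' sensor sharing a common time base. The sampling rate is inferred from
#' the median timestamp spacing; times are kept recording-relative (the
#' first timestamp becomes `t0`).
#'
#' @param path Path to a CSV file.
#' @param format `"auto"` (default; wide if more than two columns),
#'   `"long"` or `"wide"`.
#' @return A list of [seismic_trace()] objects, one per sensor column.
#' @details Non-monotone timestamps are rejected with an error naming the
#'   first offending data row. If any timestamp spacing deviates from the
#'   median spacing by more than 1%, a warning is issued and downstream
#'   alignment (which resamples onto a common grid) is required.
#' @export
read_traces <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected at least columns time,amplitude")
  if (nrow(df) < 2L) stop("need at least 2 samples to infer a sampling rate")
  tm <- as.numeric(df[[1L]])
  dt <- diff(tm)
  bad <- which(dt <= 0)
  if (length(bad))
    stop(sprintf(
      "timestamps must be strictly increasing; first violation at data row %d (time %g followed by %g)",
      bad[1L] + 1L, tm[bad[1L]], tm[bad[1L] + 1L]))
  med <- stats::median(dt)
  fs <- 1 / med
  if (any(abs(dt - med) > 0.01 * med))
    warning("timestamp spacing varies by more than 1% from the median; ",
            "resample via align_traces() before aggregation")
  if (format == "auto") format <- if (ncol(df) > 2L) "wide" else "long"
  cols <- if (format == "long") 2L else seq(2L, ncol(df))
  ids <- names(df)[cols]
  if (format == "long" && identical(ids, "amplitude")) ids <- "s1"
  lapply(seq_along(cols), function(i) {
    seismic_trace(as.numeric(df[[cols[i]]]), fs = fs, t0 = tm[1L],
                  sensor_id = ids[i])
  })
}

#' Write traces to a wide CSV file
#'
#' Inverse of [read_traces()] for traces sharing a common grid.
#'
#' @param traces List of [seismic_trace()] with equal length, `fs`, `t0`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(length(traces) >= 1L)
  n <- lengths(lapply(traces, `[[`, "samples"))
  if (length(unique(n)) != 1L)
    stop("traces must share a common grid; use align_traces() first")
  df <- data.frame(time = trace_times(traces[[1L]]))
  for (tr in traces) df[[tr$sensor_id]] <- tr$samples
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a gait report as key/value CSV
#'
#' Writes one row per parameter with the unit embedded in the key
#' (`step_time_s`, `cadence_spm`, ...), so the file round-trips through
#' [read_gait_report()] exactly.
#'
#' @param params A `gait_parameters` object from
#'   [compute_gait_parameters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gait_report <- function(params, path) {
  if (!inherits(params, "gait_parameters"))
    stop("'params' must be a gait_parameters object")
  vals <- unclass(params)
  keys <- c(step_time_s = "step_time", cycle_time_s = "cycle_time",
            ambulation_time_s = "ambulation_time", cadence_spm = "cadence",
            velocity_cm_s = "velocity", step_length_cm = "step_length",
            n_steps = "n_steps")
  v <- unlist(vals[keys], use.names = FALSE)
  if (length(v) == 0L || all(is.na(v))) stop("empty gait parameters")
  df <- data.frame(parameter = names(keys),
                   value = vapply(vals[keys], function(x)
                     if (is.null(x)) NA_real_ else as.numeric(x), 0))
  # 15 significant digits keep the human-readable decimal (0.6, not
  # 0.59999999999999998) while round-tripping far below the 1e-9 contract
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gait report written by [write_gait_report()]
#'
#' @param path Path to the key/value CSV.
#' @return A `gait_parameters` object.
#' @export
read_gait_report <- function(path) {
  df <- utils::read.csv(path)
  v <- stats::setNames(as.numeric(df$value), df$parameter)
  structure(
    list(step_time = v[["step_time_s"]], cycle_time = v[["cycle_time_s"]],
         ambulation_time = v[["ambulation_time_s"]],
         cadence = v[["cadence_spm"]], velocity = v[["velocity_cm_s"]],
         step_length = v[["step_length_cm"]],
         n_steps = as.integer(v[["n_steps"]]),
         walkway_length_cm = NA_real_),
    class = "gait_parameters"
  )
}

#' Write footstep events to CSV
#'
#' @param events A [footstep_events()] object.
#' @param path Output path; columns `time_s,foot`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "footstep_events"))
  feet <- if (is.null(events$feet)) rep(NA_character_, length(events$times))
          else events$feet
  df <- data.frame(time_s = events$times, foot = feet)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read footstep events from CSV
#'
#' @param path Path to a CSV with columns `time_s` and optionally `foot`.
#' @param source Walk identifier to attach.
#' @return A [footstep_events()] object.
#' @export
read_events <- function(path, source = "walk") {
  df <- utils::read.csv(path)
  feet <- if ("foot" %in% names(df)) as.character(df$foot) else NULL
  if (!is.null(feet) && all(is.na(feet))) feet <- NULL
  footstep_events(as.numeric(df$time_s), feet = feet, source = source)
}

#' Read a YAML walk configuration
#'
#' Reads sensor positions, walkway length and any pipeline parameter
#' overrides from a YAML file; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A named list merged over [seismogait_config()] defaults.
#' @export
read_walk_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(seismogait_config, raw)
}
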