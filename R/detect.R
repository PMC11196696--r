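#' Pipeline configuration
#'
#' All tunable parameters of the detection pipeline in one validated
#' object. The defaults are the method's published operating point: a
#' 0.2 s spherical structuring element (the duration of an average
#' single footstep), 0.1 s radii for the Hamming and rectangular
#' post-filters, a 50 ms minimum inter-peak distance, and a peak-height
#' threshold at the 95th percentile of the min-max normalized
#' amplitudes. The rolling-maximum aggregation window defaults to
#' 0.08 s so that it spans at least one period of the footstep
#' transient's dominant frequency and therefore extracts its upper
#' envelope. Unknown keys are rejected.
#'
#' @param agg_window_s Rolling-maximum aggregation window (s).
#' @param se_radius_s Structuring-element radius (s).
#' @param se_shape `"spherical"` or `"flat"`.
#' @param se_height Peak height of the spherical SE.
#' @param hamming_radius_s Hamming smoothing radius (s).
#' @param rect_radius_s Rectangular (moving-average) filter radius (s).
#' @param min_distance_s Minimum distance between detected peaks (s).
#' @param height_percentile Peak-height threshold percentile in (0, 100).
#' @param renormalize Re-min-max-normalize the filtered signal before
#'   thresholding (the threshold rule is stated on normalized
#'   amplitudes).
#' @param walkway_length_cm Active walkway length (cm).
#' @param fs Nominal sampling rate (Hz).
#' @return A named list of class `seismogait_config`.
#' @export
seismogait_config <- function(agg_window_s = 0.08,
                              se_radius_s = 0.2,
                              se_shape = c("spherical", "flat"),
                              se_height = 1,
                              hamming_radius_s = 0.1,
                              rect_radius_s = 0.1,
                              min_distance_s = 0.05,
                              height_percentile = 95,
                              renormalize = TRUE,
                              walkway_length_cm = 488,
                              fs = 100) {
  se_shape <- match.arg(se_shape)
  cfg <- list(agg_window_s = agg_window_s, se_radius_s = se_radius_s,
              se_shape = se_shape, se_height = se_height,
              hamming_radius_s = hamming_radius_s,
              rect_radius_s = rect_radius_s,
              min_distance_s = min_distance_s,
              height_percentile = height_percentile,
              renormalize = isTRUE(renormalize),
              walkway_length_cm = walkway_length_cm, fs = fs)
  num <- cfg[setdiff(names(cfg), c("se_shape", "renormalize"))]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), TRUE)))
    stop("all numeric configuration values must be finite scalars")
  if (cfg$agg_window_s < 0) stop("'agg_window_s' must be >= 0")
  stopifnot(cfg$se_radius_s > 0, cfg$hamming_radius_s > 0,
            cfg$rect_radius_s > 0, cfg$min_distance_s > 0,
            cfg$walkway_length_cm > 0, cfg$fs > 0)
  if (cfg$height_percentile <= 0 || cfg$height_percentile >= 100)
    stop("'height_percentile' must be in (0, 100)")
  class(cfg) <- "seismogait_config"
  cfg
}

# symmetric convolution with reflect padding; unit-sum kernel => DC gain 1
smooth_reflect <- function(x, kernel) {
  kernel <- kernel / sum(kernel)
  m <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  if (length(kernel) > n) stop("filter kernel longer than signal")
  if (m == 0L) return(x * sum(kernel))
  pad <- c(x[(m + 1L):2L], x, x[(n - 1L):(n - m)])
  y <- stats::filter(pad, kernel, method = "convolution", sides = 2)
  as.numeric(y)[(m + 1L):(m + n)]
}

#' Hamming smoothing filter
#'
#' Convolves the signal with a unit-sum Hamming window of length
#' `2 * round(radius * fs) + 1` (21 samples for the default 0.1 s radius
#' at 100 Hz), reflect-padded so the output has the input's length and
#' exactly unit DC gain. Boosts genuine peaks relative to sample-scale
#' jitter while smoothing.
#'
#' @param signal Numeric vector or [seismic_trace()].
#' @param radius Filter radius in seconds (> 0).
#' @param fs Sampling rate in Hz; taken from the trace if one is given.
#' @return Same type as `signal`.
#' @export
hamming_smooth <- function(signal, radius = 0.1, fs = NULL) {
  if (radius <= 0) stop("'radius' must be > 0")
  if (inherits(signal, "seismic_trace")) fs <- signal$fs
  if (is.null(fs)) stop("'fs' required for numeric input")
  len <- 2L * round(radius * fs) + 1L
  kern <- if (len == 1L) 1 else signal::hamming(len)
  morph_apply(signal, function(x) smooth_reflect(x, kern))
}

#' Rectangular (moving-average) filter
#'
#' Convolves with a unit-sum rectangular kernel of length
#' `2 * round(radius * fs) + 1`, reflect-padded. Peaks closer than the
#' kernel support merge into a single local maximum, eliminating closely
#' adjoining double peaks before peak detection.
#'
#' @inheritParams hamming_smooth
#' @return Same type as `signal`.
#' @export
rect_filter <- function(signal, radius = 0.1, fs = NULL) {
  if (radius <= 0) stop("'radius' must be > 0")
  if (inherits(signal, "seismic_trace")) fs <- signal$fs
  if (is.null(fs)) stop("'fs' required for numeric input")
  len <- 2L * round(radius * fs) + 1L
  morph_apply(signal, function(x) smooth_reflect(x, rep(1, len)))
}

# local maxima with plateaus resolved to their midpoint sample (lower
# middle for even plateau lengths); endpoints are never maxima
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j])
        peaks <- c(peaks, (i + j) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# greedy pruning: highest peak first (earlier index on ties), drop any
# candidate within min_dist samples of an already-kept peak
prune_min_distance <- function(idx, heights, min_dist) {
  if (length(idx) <= 1L) return(idx)
  ord <- idx[order(-heights, idx)]
  kept <- integer(0)
  for (p in ord)
    if (length(kept) == 0L || all(abs(p - kept) >= min_dist))
      kept <- c(kept, p)
  sort(kept)
}

#' Detect footstep peaks in a filtered signal
#'
#' Min-max normalizes the signal (unless `config$renormalize` is FALSE),
#' finds strict local maxima (plateaus resolved to their midpoint),
#' keeps those at or above the `height_percentile`-th percentile of the
#' normalized amplitude distribution, and greedily prunes survivors so
#' that no two peaks are closer than `min_distance_s` (higher peak wins;
#' ties go to the earlier peak). Timestamps are `t0 + index / fs`.
#'
#' The percentile is computed over all samples of the signal, so the
#' rule presumes footstep transients are temporally sparse within the
#' recording (recordings normally bracket the walk with quiet periods).
#'
#' @param signal Numeric vector or [seismic_trace()] of the filtered
#'   composite signal.
#' @param config A [seismogait_config()].
#' @param fs,t0 Sampling rate and start time for numeric input (taken
#'   from the trace otherwise).
#' @param source Walk identifier to attach to the events.
#' @return A [footstep_events()] object. An empty or constant signal
#'   yields zero events with a warning.
#' @export
detect_peaks <- function(signal, config = seismogait_config(), fs = NULL,
                         t0 = 0, source = "walk") {
  stopifnot(inherits(config, "seismogait_config"))
  if (inherits(signal, "seismic_trace")) {
    fs <- signal$fs; t0 <- signal$t0; x <- signal$samples
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("'fs' required for numeric input")
  }
  if (length(x) == 0L || diff(range(x)) == 0) {
    warning("empty or constant signal: no events detected")
    return(footstep_events(numeric(0), source = source))
  }
  if (config$renormalize) {
    rng <- range(x)
    x <- (x - rng[1L]) / (rng[2L] - rng[1L])
  }
  thr <- stats::quantile(x, config$height_percentile / 100, names = FALSE)
  idx <- local_maxima(x)
  idx <- idx[x[idx] >= thr]
  min_dist <- ceiling(config$min_distance_s * fs - 1e-9)
  idx <- prune_min_distance(idx, x[idx], min_dist)
  footstep_events(t0 + (idx - 1L) / fs, source = source)
}

#' Extract footstep events from raw traces
#'
#' Runs the full step-extraction pipeline: per-trace min-max
#' normalization and mean subtraction, temporal alignment onto a common
#' grid, rolling-maximum aggregation across sensors, compound top-hat
#' filtering with a spherical structuring element, Hamming and
#' rectangular smoothing, renormalization, and constrained peak
#' detection. Deterministic for fixed inputs and configuration; only
#' peak timestamps (never amplitudes) leave this stage.
#'
#' @param traces List of [seismic_trace()] (>= 1).
#' @param config A [seismogait_config()].
#' @param source Walk identifier to attach to the events.
#' @return A [footstep_events()] object.
#' @examples
#' sim <- simulate_walk(walk_scenario(n_steps = 8, seed = 42))
#' ev <- extract_footsteps(sim$traces)
#' length(ev$times)  # 8
#' @export
extract_footsteps <- function(traces, config = seismogait_config(),
                              source = "walk") {
  stopifnot(inherits(config, "seismogait_config"))
  if (length(traces) == 0L) stop("need at least one trace")
  normed <- lapply(traces, detrend_normalize)
  aligned <- align_traces(normed)
  agg <- aggregate_max(aligned, window = config$agg_window_s)
  se <- structuring_element(config$se_radius_s, fs = agg$fs,
                            shape = config$se_shape,
                            height = config$se_height)
  y <- ctf(agg, se)
  y <- hamming_smooth(y, radius = config$hamming_radius_s)
  y <- rect_filter(y, radius = config$rect_radius_s)
  detect_peaks(y, config = config, source = source)
}
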