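#' Walk scenario for the synthetic-data generator
#'
#' Describes one simulated pass over the walkway. The defaults emulate
#' the validation study's conditions: a 4.88 m active walkway with three
#' geophone-type sensors on the floor 1.5 m apart on alternating sides,
#' 100 Hz sampling, and a mean step interval of 0.604 s. Each footstep
#' injects a Gaussian-windowed cosine burst (a Gabor wavelet, the
#' standard synthetic seismic impulse) centred at the step time, with
#' per-sensor propagation delay and linear amplitude attenuation with
#' distance; traces additionally carry white measurement noise and
#' sub-2 Hz drift (sinusoid plus random walk), the noise regime the
#' compound top-hat filter is designed to attenuate. Recordings bracket
#' the walk with quiet lead-in/lead-out periods, as real session
#' recordings do.
#'
#' @param n_steps Number of steps in the walk.
#' @param step_interval_mean Mean inter-step interval (s).
#' @param step_interval_sd Within-walk interval SD (s); intervals are
#'   drawn truncated at 3 SD to keep orderings physical.
#' @param walkway_length_cm Active walkway length (cm).
#' @param sensor_positions Matrix with one `(x, y)` row per sensor (m).
#' @param wave_speed Propagation speed through the floor (m/s).
#' @param attenuation_per_m Linear amplitude loss per metre (fraction).
#' @param impulse_freq Dominant frequency of the footstep burst (Hz).
#' @param impulse_decay Gaussian envelope SD of the burst (s).
#' @param impulse_amp Source amplitude of each footstep burst.
#' @param noise_sd White noise SD (amplitude units).
#' @param drift_amp Amplitude of the low-frequency drift.
#' @param drift_freq Frequency of the sinusoidal drift component (Hz),
#'   below the ~2 Hz band of natural human-walking energy.
#' @param lead_in_s,lead_out_s Quiet recording before/after the walk (s).
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer; fixes all randomness of the walk.
#' @return A named list of class `walk_scenario`.
#' @export
walk_scenario <- function(n_steps = 8,
                          step_interval_mean = 0.604,
                          step_interval_sd = 0.03,
                          walkway_length_cm = 488,
                          sensor_positions = rbind(c(0.94, 0.3),
                                                   c(2.44, -0.3),
                                                   c(3.94, 0.3)),
                          wave_speed = 500,
                          attenuation_per_m = 0.08,
                          impulse_freq = 22,
                          impulse_decay = 0.045,
                          impulse_amp = 1,
                          noise_sd = 0.04,
                          drift_amp = 0.08,
                          drift_freq = 0.5,
                          lead_in_s = 12,
                          lead_out_s = 12,
                          fs = 100,
                          seed = NULL) {
  sc <- list(n_steps = as.integer(n_steps),
             step_interval_mean = step_interval_mean,
             step_interval_sd = step_interval_sd,
             walkway_length_cm = walkway_length_cm,
             sensor_positions = sensor_positions,
             wave_speed = wave_speed,
             attenuation_per_m = attenuation_per_m,
             impulse_freq = impulse_freq, impulse_decay = impulse_decay,
             impulse_amp = impulse_amp, noise_sd = noise_sd,
             drift_amp = drift_amp, drift_freq = drift_freq,
             lead_in_s = lead_in_s, lead_out_s = lead_out_s,
             fs = fs, seed = seed)
  stopifnot(sc$n_steps >= 1L, sc$step_interval_mean > 0,
            sc$step_interval_sd >= 0, sc$walkway_length_cm > 0,
            is.matrix(sc$sensor_positions), ncol(sc$sensor_positions) == 2L,
            sc$wave_speed > 0, sc$attenuation_per_m >= 0,
            sc$impulse_freq > 0, sc$impulse_decay > 0, sc$impulse_amp > 0,
            sc$noise_sd >= 0, sc$drift_amp >= 0, sc$drift_freq > 0,
            sc$lead_in_s >= 0, sc$lead_out_s >= 0, sc$fs > 0)
  class(sc) <- "walk_scenario"
  sc
}

# run code under a fixed seed if one is given, else use the current RNG
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a multi-sensor walk recording
#'
#' Draws step times as the cumulative sum of truncated-normal intervals,
#' advances step positions uniformly along the walkway, and synthesizes
#' each sensor's trace as the sum over steps of a Gabor wavelet
#' `A * exp(-(t - t_k - d_k)^2 / (2 * tau^2)) * cos(2 pi f (t - t_k - d_k))`
#' centred at the step time plus the propagation delay
#' `d_k = distance / wave_speed`, with amplitude
#' `A = amp * max(0, 1 - attenuation_per_m * distance)`, plus white noise
#' and drift. Deterministic given `scenario$seed`.
#'
#' @param scenario A [walk_scenario()].
#' @return A list with `traces` (list of [seismic_trace()], `t0 = 0`) and
#'   `truth` (list with `step_times` (s), `step_positions_cm`, and `gait`,
#'   the ground-truth `gait_parameters` computed from the step times).
#' @export
simulate_walk <- function(scenario = walk_scenario()) {
  stopifnot(inherits(scenario, "walk_scenario"))
  sc <- scenario
  maybe_with_seed(sc$seed, {
    ints <- if (sc$n_steps > 1L) {
      lo <- sc$step_interval_mean - 3 * sc$step_interval_sd
      hi <- sc$step_interval_mean + 3 * sc$step_interval_sd
      pmin(pmax(stats::rnorm(sc$n_steps - 1L, sc$step_interval_mean,
                             sc$step_interval_sd), lo), hi)
    } else numeric(0)
    if (any(ints <= 0)) stop("step intervals must stay positive; ",
                             "reduce 'step_interval_sd'")
    # random sub-sample phase: a real walk never starts aligned with the
    # sampling grid, and a grid-aligned first contact would be the one
    # event with zero quantization error, biasing interval estimates
    step_times <- sc$lead_in_s + stats::runif(1, 0, 1 / sc$fs) +
      c(0, cumsum(ints))
    t <- seq(0, max(step_times) + sc$lead_out_s, by = 1 / sc$fs)
    n <- length(t)
    # contacts advance uniformly but land inside the active area: the
    # walker stands at the walkway end, so the first and last footfalls
    # fall about half a step length inside the measurement zone
    xpos_m <- (seq_len(sc$n_steps) - 0.5) / sc$n_steps *
      sc$walkway_length_cm / 100
    traces <- lapply(seq_len(nrow(sc$sensor_positions)), function(s) {
      p <- sc$sensor_positions[s, ]
      sig <- numeric(n)
      for (k in seq_len(sc$n_steps)) {
        dist <- sqrt((xpos_m[k] - p[1L])^2 + p[2L]^2)
        amp <- sc$impulse_amp * max(0, 1 - sc$attenuation_per_m * dist)
        tt <- t - step_times[k] - dist / sc$wave_speed
        sig <- sig + amp * exp(-tt^2 / (2 * sc$impulse_decay^2)) *
          cos(2 * pi * sc$impulse_freq * tt)
      }
      drift <- sc$drift_amp * sin(2 * pi * sc$drift_freq * t +
                                    stats::runif(1, 0, 2 * pi)) +
        sc$drift_amp * 0.5 * cumsum(stats::rnorm(n)) / sqrt(n)
      seismic_trace(sig + stats::rnorm(n, 0, sc$noise_sd) + drift,
                    fs = sc$fs, t0 = 0, sensor_id = paste0("s", s),
                    position = p)
    })
    truth_gait <- if (sc$n_steps >= 2L)
      compute_gait_parameters(footstep_events(step_times, source = "truth"),
                              sc$walkway_length_cm)
    else NULL
    list(traces = traces,
         truth = list(step_times = step_times,
                      step_positions_cm = xpos_m * 100,
                      gait = truth_gait))
  })
}

#' Simulate a cohort of walks and run the detection pipeline on each
#'
#' Generates `n_walks` walks whose step counts are drawn uniformly from
#' `n_steps_range` and whose per-walk mean step intervals are drawn from
#' a normal distribution with SD `interval_mean_sd` around the
#' scenario's mean (mimicking between-walk variability in a cohort),
#' runs [extract_footsteps()] on each, and returns paired ground-truth
#' and recovered gait parameters suitable for the agreement statistics.
#'
#' @param n_walks Number of walks (>= 2).
#' @param scenario Base [walk_scenario()]; per-walk copies vary the seed,
#'   step count and mean interval.
#' @param seed Integer master seed; all per-walk seeds derive from it.
#' @param n_steps_range Integer range `c(lo, hi)` for steps per walk.
#' @param interval_mean_sd Between-walk SD of the mean step interval (s).
#' @param config [seismogait_config()] for the detection pipeline.
#' @param sensors Optional integer vector: use only these sensors (e.g.
#'   `2` for a single-seismograph run).
#' @return A `data.frame` with one row per walk: `walk_id`, `n_steps`,
#'   `n_detected`, `exact` (logical), `mae_ms` (mean absolute event-time
#'   error, only when the count is exact), and `truth_*` / `est_*`
#'   columns for the six gait parameters. Walks with fewer than two
#'   recovered events keep `NA` estimates rather than failing.
#' @export
simulate_cohort <- function(n_walks = 50, scenario = walk_scenario(),
                            seed = 1, n_steps_range = c(6L, 12L),
                            interval_mean_sd = 0.092,
                            config = seismogait_config(),
                            sensors = NULL) {
  stopifnot(n_walks >= 2L)
  par_names <- c("step_time", "cycle_time", "ambulation_time", "cadence",
                 "velocity", "step_length")
  draws <- withr::with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_walks),
         steps = sample(seq.int(n_steps_range[1L], n_steps_range[2L]),
                        n_walks, replace = TRUE),
         # truncate the between-walk distribution at 2 SD: the cohorts
         # this emulates are healthy adults walking (not running), with
         # cadence spanning roughly 101 +/- 2 * 14 steps/min
         means = pmin(pmax(stats::rnorm(n_walks,
                                        scenario$step_interval_mean,
                                        interval_mean_sd),
                           scenario$step_interval_mean -
                             2 * interval_mean_sd),
                      scenario$step_interval_mean + 2 * interval_mean_sd))
  })
  rows <- lapply(seq_len(n_walks), function(i) {
    sc <- scenario
    sc$seed <- draws$seeds[i]
    sc$n_steps <- draws$steps[i]
    sc$step_interval_mean <- draws$means[i]
    sim <- simulate_walk(sc)
    traces <- if (is.null(sensors)) sim$traces else sim$traces[sensors]
    ev <- extract_footsteps(traces, config = config,
                            source = sprintf("walk%03d", i))
    truth <- as.data.frame(sim$truth$gait)
    est <- if (length(ev$times) >= 2L)
      as.data.frame(compute_gait_parameters(ev, sc$walkway_length_cm))
    else as.data.frame(stats::setNames(as.list(rep(NA_real_, 7L)),
                                       c(par_names, "n_steps")))
    exact <- length(ev$times) == sc$n_steps
    mae <- if (exact && sc$n_steps > 0L)
      mean(abs(ev$times - sim$truth$step_times)) * 1000 else NA_real_
    out <- data.frame(walk_id = sprintf("walk%03d", i),
                      n_steps = sc$n_steps, n_detected = length(ev$times),
                      exact = exact, mae_ms = mae)
    for (p in par_names) {
      out[[paste0("truth_", p)]] <- truth[[p]]
      out[[paste0("est_", p)]] <- est[[p]]
    }
    out
  })
  do.call(rbind, rows)
}
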