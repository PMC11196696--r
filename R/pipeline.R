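#' Run the full pipeline on one walk
#'
#' Detects footsteps in the given traces (or a simulated walk when
#' `traces` is `NULL`), assigns foot labels, computes gait parameters,
#' and optionally writes the events CSV, the gait report CSV and a
#' plain-text provenance log (configuration, seed, package version) to
#' `out_dir`.
#'
#' @param traces List of [seismic_trace()], or `NULL` to simulate
#'   `scenario`.
#' @param config A [seismogait_config()].
#' @param meta A [walk_metadata()]; supplies walkway length, first foot
#'   and the walk id.
#' @param scenario [walk_scenario()] used when `traces` is `NULL`.
#' @param out_dir Optional output directory for artifacts.
#' @return A list with `events` ([footstep_events()]), `gait`
#'   (`gait_parameters`), and `truth` (ground truth when simulated,
#'   else `NULL`).
#' @export
run_walk <- function(traces = NULL, config = seismogait_config(),
                     meta = walk_metadata(), scenario = walk_scenario(),
                     out_dir = NULL) {
  stopifnot(inherits(config, "seismogait_config"),
            inherits(meta, "walk_metadata"))
  truth <- NULL
  if (is.null(traces)) {
    sim <- simulate_walk(scenario)
    traces <- sim$traces
    truth <- sim$truth
  }
  events <- extract_footsteps(traces, config = config,
                              source = meta$walk_id)
  events <- assign_feet(events, meta$first_foot)
  gait <- compute_gait_parameters(events, meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(out_dir,
                                   paste0(meta$walk_id, "_events.csv")))
    write_gait_report(gait, file.path(out_dir,
                                      paste0(meta$walk_id, "_gait.csv")))
    log <- c(sprintf("walk_id: %s", meta$walk_id),
             sprintf("package: seismogait %s",
                     as.character(utils::packageVersion("seismogait"))),
             sprintf("seed: %s",
                     if (is.null(scenario$seed)) "NA" else scenario$seed),
             sprintf("config: %s",
                     paste(names(unclass(config)),
                           vapply(unclass(config), format, ""),
                           sep = "=", collapse = " ")))
    writeLines(log, file.path(out_dir, paste0(meta$walk_id, "_run.log")))
  }
  list(events = events, gait = gait, truth = truth)
}

#' Run a synthetic validation study
#'
#' Simulates a cohort of walks, recovers their gait parameters through
#' the detection pipeline, and compares recovered against ground-truth
#' values with the full agreement battery (paired t-test, regression,
#' Pearson correlation, Bland-Altman), one report per gait parameter —
#' a synthetic analogue of validating the seismograph system against a
#' reference system.
#'
#' @param n_walks Number of walks in the cohort.
#' @param scenario Base [walk_scenario()].
#' @param seed Master seed for the cohort.
#' @param config [seismogait_config()] for detection.
#' @param parameters Character vector of gait parameters to report on.
#' @return A list with `cohort` (the [simulate_cohort()] data frame) and
#'   `reports` (named list of [agreement_report()]s).
#' @export
run_validation_study <- function(n_walks = 50,
                                 scenario = walk_scenario(),
                                 seed = 1,
                                 config = seismogait_config(),
                                 parameters = c("step_time", "cycle_time",
                                                "ambulation_time",
                                                "cadence", "velocity",
                                                "step_length")) {
  cohort <- simulate_cohort(n_walks = n_walks, scenario = scenario,
                            seed = seed, config = config)
  reports <- lapply(parameters, function(p) {
    agreement_report(cohort[[paste0("est_", p)]],
                     cohort[[paste0("truth_", p)]],
                     parameter_name = p)
  })
  names(reports) <- parameters
  list(cohort = cohort, reports = reports)
}
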