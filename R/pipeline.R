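# End-to-end workflow: simulate -> preprocess -> featurize -> gate ->
# classify -> report, under a single serializable configuration.

#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of a full run. Defaults equal the study settings:
#' 256 Hz, fifth-order filters, Welch window 637 / overlap 636, 75/25
#' holdout repeated 10 times, 3 s per selection.
#'
#' @param n_subjects,reps_per_class Cohort size (defaults give 800
#'   recordings).
#' @param sim Base [sim_config()] for the generator.
#' @param classifier,feature_set,split,repeats,itr_T Passed to
#'   [bci_cascade()].
#' @param seed Master seed for the whole run.
#' @param out_dir Optional directory for artifacts (report JSON, feature
#'   tables).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_subjects = 10, reps_per_class = 10,
                       sim = sim_config(), classifier = "rf",
                       feature_set = "consensus16", split = 0.75,
                       repeats = 10, itr_T = 3, seed = 1, out_dir = NULL) {
  structure(list(n_subjects = n_subjects, reps_per_class = reps_per_class,
                 sim = sim, classifier = classifier,
                 feature_set = feature_set, split = split,
                 repeats = repeats, itr_T = itr_T, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- unclass(config)
  plain$sim <- unclass(plain$sim)
  plain$sim$trajectory <- unclass(plain$sim$trajectory)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- plain$sim$trajectory
  sim <- do.call(sim_config, c(plain$sim[setdiff(names(plain$sim),
                                                 c("trajectory", "nfft"))],
                               list(trajectory = trajectory_spec(
                                 tr$name, tr$cycle_rate_hz))))
  do.call(run_config, c(plain[setdiff(names(plain), "sim")],
                        list(sim = sim)))
}

#' Run the full pipeline under one configuration
#'
#' Simulates the cohort, fits and evaluates the cascade, and assembles a
#' JSON-serializable report (per-subject and averaged accuracies and ITR,
#' plus segment bookkeeping counts satisfying
#' `segments_tested = gate_passed + gate_rejected`). Stage boundaries are
#' logged with counts. A fixed seed makes two runs produce identical
#' reports.
#'
#' @param config A [run_config()].
#' @param verbose Log stage boundaries.
#' @return List with `cascade` (the fitted `bci_cascade`) and `report`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulate: %d subjects x %d reps -> %d recordings",
      config$n_subjects, config$reps_per_class,
      config$n_subjects * config$reps_per_class * 8)
  cohort <- synth_cohort(config$n_subjects, config$reps_per_class,
                         config$sim, seed = config$seed)
  casc <- bci_cascade(cohort, classifier = config$classifier,
                      feature_set = config$feature_set,
                      split = config$split, repeats = config$repeats,
                      seed = config$seed, itr_T = config$itr_T,
                      verbose = verbose)
  say("cascade: tested %d segment decisions (%d passed + %d rejected)",
      casc$counts$segments_tested, casc$counts$gate_passed,
      casc$counts$gate_rejected)
  report <- list(classifier = casc$classifier,
                 n_features = length(casc$feature_ids),
                 n_recordings = casc$n_recordings,
                 n_segments = casc$n_segments,
                 per_subject = casc$per_subject,
                 average = casc$average,
                 counts = casc$counts,
                 seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_run_config(config, file.path(config$out_dir, "run_config.json"))
    say("report written to %s", config$out_dir)
  }
  list(cascade = casc, report = report)
}
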