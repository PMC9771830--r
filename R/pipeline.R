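#' Default study configuration
#'
#' A nested list describing one synthetic study: arena and task geometry,
#' trajectory generator, voxel tuning specification, signal cleaning,
#' direction binning, classifier, fold and permutation settings, the
#' session-exclusion rule, simulated groups/conditions, and the master
#' seed. Every randomized stage derives its own seed from the master seed
#' via [derive_seed()]. Configurations round-trip losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' Defaults emulate the study conditions: a circular arena, 5 objects x 6
#' feedback repetitions, ~17.4 min of free navigation per session sampled
#' at 10 Hz, TR 2.36 s, a two-TR hemodynamic lag, six 60-degree direction
#' bins, 1-s minimum events, an L2 multinomial classifier with C = 1,
#' three temporal folds, and 1000-iteration permutation nulls.
#'
#' @return A named list of class `study_config`.
#' @export
default_config <- function() {
  structure(list(
    arena = list(radius_vm = 25, unreal_units_per_vm = 62.5),
    task = list(n_repetitions = 6, memory_noise_sd = 8, noise_decay = 0.75,
                omission_prob = 0, exclusion_missing_frac = 1 / 3),
    trajectory = list(duration = 1041.6, dt = 0.1, turn_volatility = 40,
                      mean_speed = 2, speed_cv = 0.2),
    bold = list(TR = 2.36, lag_TRs = 2, n_voxels = 100, tuning_sd = 30,
                gain = 0.5, baseline = 100, noise_sd = 2,
                fraction_tuned = 0.5, drift_amplitude = 1),
    cleaning = list(cutoff_s = 128, n_confounds_used = 10),
    binning = list(n_bins = 6),
    events = list(min_duration = 1, min_speed = 0.05),
    classifier = list(C = 1, tolerance = 1e-4, max_iterations = 1000),
    folds = list(k = 3),
    exclusion = list(min_per_class = 3),
    permutation = list(n_iterations = 1000),
    study = list(n_subjects = 10,
                 conditions = list(high_gain = list(gain = 0.6),
                                   low_gain = list(gain = 0.3))),
    seed = 1L), class = "study_config")
}

#' Build a study configuration from overrides
#'
#' @param ... Named top-level sections (e.g. `trajectory = list(duration =
#'   300)`) merged recursively into [default_config()].
#' @return A `study_config`.
#' @export
study_config <- function(...) {
  cfg <- default_config()
  dots <- list(...)
  for (i in seq_along(dots)) {      # repeated sections merge in order
    nm <- names(dots)[i]
    if (is.list(cfg[[nm]]) && is.list(dots[[i]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[i]])
    } else {
      cfg[[nm]] <- dots[[i]]
    }
  }
  cfg
}

#' Write / read a study configuration as YAML
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "study_config")
}

#' Run the full pipeline for one simulated subject session
#'
#' Executes simulate -> generate -> clean -> extract -> decode -> tune for
#' a single subject in a single condition: trajectory simulation, feedback
#' phase, tuned BOLD generation, signal cleaning, direction-event
#' extraction, the class-distribution check (failing sessions are marked
#' excluded rather than raising an error, mirroring participant
#' exclusion), cross-validated decoding, the confusion function, and the
#' Gaussian precision fit. Optionally also computes the per-subject
#' permutation null.
#'
#' @param config A `study_config`.
#' @param subject_id Integer subject index (seeds derive from it).
#' @param condition Name of a condition in `config$study$conditions`, or
#'   `NULL` for the base configuration.
#' @param run_permutation Also compute the permutation null (costly).
#' @param out_dir Optional directory; when given, the events TSV and a
#'   per-subject JSON summary are written there.
#' @return A list: `subject_id`, `condition`, `excluded`, `reason`,
#'   `trajectory`, `feedback`, `behavior`, `events`, `example_set`,
#'   `decoding`, `confusion`, `fit`, `null` (if requested), `summary`
#'   (one-row tibble).
#' @export
run_subject <- function(config, subject_id, condition = NULL,
                        run_permutation = FALSE, out_dir = NULL) {
  cond_idx <- 0L
  bold_cfg <- config$bold
  if (!is.null(condition)) {
    cond_idx <- match(condition, names(config$study$conditions))
    if (is.na(cond_idx)) stop("unknown condition: ", condition)
    bold_cfg <- utils::modifyList(bold_cfg,
                                  config$study$conditions[[condition]])
  }
  seed_of <- function(stage) {
    derive_seed(config$seed, subject = subject_id, condition = cond_idx,
                stage = stage)
  }

  arena <- arena_spec(config$arena$radius_vm, config$arena$unreal_units_per_vm)
  traj <- simulate_trajectory(
    arena, duration = config$trajectory$duration, dt = config$trajectory$dt,
    turn_volatility = config$trajectory$turn_volatility,
    mean_speed = config$trajectory$mean_speed,
    speed_cv = config$trajectory$speed_cv, seed = seed_of("trajectory"))

  objects <- random_object_set(arena, seed = seed_of("feedback"))
  feedback <- simulate_feedback_phase(
    arena, objects, memory_noise_sd = config$task$memory_noise_sd,
    n_repetitions = config$task$n_repetitions,
    noise_decay = config$task$noise_decay,
    omission_prob = config$task$omission_prob, seed = seed_of("feedback"))
  behavior <- behavior_summary(feedback)

  spec <- voxel_tuning_spec(
    n_voxels = bold_cfg$n_voxels, tuning_sd = bold_cfg$tuning_sd,
    gain = bold_cfg$gain, baseline = bold_cfg$baseline,
    noise_sd = bold_cfg$noise_sd, fraction_tuned = bold_cfg$fraction_tuned)
  run <- generate_tuned_bold(traj, spec, TR = bold_cfg$TR,
                             lag = bold_cfg$lag_TRs * bold_cfg$TR,
                             drift_amplitude = bold_cfg$drift_amplitude,
                             seed = seed_of("bold"))
  cleaned <- clean_signal(run, cutoff_s = config$cleaning$cutoff_s,
                          n_confounds_used = config$cleaning$n_confounds_used)

  binning <- direction_binning(config$binning$n_bins)
  events <- extract_events(traj, binning,
                           min_duration = config$events$min_duration,
                           min_speed = config$events$min_speed)
  es <- events_to_examples(events, cleaned, TR = bold_cfg$TR,
                           lag_TRs = bold_cfg$lag_TRs, binning = binning,
                           session_id = paste0("sub-", subject_id))

  check <- check_class_distribution(es,
                                    min_per_class = config$exclusion$min_per_class,
                                    k_folds = config$folds$k)
  out <- list(subject_id = subject_id, condition = condition,
              excluded = !check$pass, reason = check$reason,
              trajectory = traj, feedback = feedback, behavior = behavior,
              events = events, example_set = es)

  if (check$pass) {
    cspec <- classifier_spec(config$classifier$C, config$classifier$tolerance,
                             config$classifier$max_iterations)
    folds <- make_folds(es, k = config$folds$k)
    dec <- cross_validate(es, cspec, folds, seed = seed_of("decode"))
    cf <- confusion_function(dec$prob, dec$y_true, binning$centers)
    fit <- fit_tuning(cf)
    out$decoding <- dec
    out$confusion <- cf
    out$fit <- fit
    if (run_permutation) {
      out$null <- permutation_null(es, cspec, folds,
                                   n_iterations = config$permutation$n_iterations,
                                   seed = seed_of("permutation"))
    }
  }

  out$summary <- tibble::tibble(
    subject = subject_id,
    condition = if (is.null(condition)) NA_character_ else condition,
    n_examples = length(es$y),
    n_dropped = es$n_dropped,
    excluded = !check$pass,
    balanced_accuracy = if (check$pass) out$decoding$balanced_accuracy else NA_real_,
    tau = if (check$pass) out$fit$tau else NA_real_,
    learning_change = tryCatch(learning_change(behavior),
                               error = function(e) NA_real_))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events_tsv(events, file.path(out_dir,
                                       sprintf("sub-%03d_events.tsv", subject_id)))
    jsonlite::write_json(out$summary,
                         file.path(out_dir,
                                   sprintf("sub-%03d_summary.json", subject_id)),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run a full synthetic study
#'
#' Runs [run_subject()] for every subject in every condition, aggregates
#' the per-subject summaries into a tidy long-format table, and computes
#' the group-level statistics the pipeline reports directly: a one-sided
#' t-test of balanced accuracy against chance per condition (Holm-corrected
#' across conditions) and a paired contrast between the first two
#' conditions. Byte-identical outputs are reproduced by re-running with
#' the same configuration.
#'
#' @param config A `study_config`.
#' @param out_dir Optional output directory for the tidy TSV and a JSON
#'   run manifest.
#' @return A list with `table` (tidy tibble: subject, condition,
#'   n_examples, excluded, balanced_accuracy, tau, learning_change),
#'   `tests` (tibble of group tests), `contrast` (paired-contrast tibble
#'   or NULL), `n_excluded`.
#' @export
run_study <- function(config, out_dir = NULL) {
  conds <- names(config$study$conditions)
  if (is.null(conds)) conds <- list(NULL)
  rows <- list()
  for (cond in conds) {
    for (s in seq_len(config$study$n_subjects)) {
      rows[[length(rows) + 1]] <-
        run_subject(config, s, condition = cond)$summary
    }
  }
  table <- do.call(rbind, rows)
  usable <- table[!table$excluded, ]
  if (nrow(usable) == 0) stop("all subjects excluded; no decodable sessions")

  tests <- do.call(rbind, lapply(unique(usable$condition), function(cond) {
    sc <- usable$balanced_accuracy[usable$condition %in% cond]
    tt <- t_test_vs_chance(sc)
    tt$condition <- cond
    tt$mean_score <- mean(sc)
    tt$n <- length(sc)
    tt
  }))
  tests$p_adjusted <- holm_correct(tests$p_one_sided)

  contrast <- NULL
  if (length(conds) >= 2 && !is.null(conds[[1]])) {
    a <- table[table$condition == conds[[1]], ]
    b <- table[table$condition == conds[[2]], ]
    ok <- !a$excluded & !b$excluded
    if (sum(ok) >= 2) {
      contrast <- paired_contrast(a$balanced_accuracy[ok],
                                  b$balanced_accuracy[ok])
      contrast$conditions <- paste(conds[[1]], "-", conds[[2]])
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_tsv(table, file.path(out_dir, "study_results.tsv"))
    manifest <- list(package_version = as.character(utils::packageVersion("navdecode")),
                     config = unclass(config),
                     files = c("study_results.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(table = table, tests = tests, contrast = contrast,
       n_excluded = sum(table$excluded))
}
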