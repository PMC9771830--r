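#' Write / read a trajectory as TSV
#'
#' Tab-separated table with header row and columns `t` (s), `x`, `y` (vm),
#' `heading` (degrees), `speed` (vm/s).
#'
#' @param traj Trajectory tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @param dt Sampling step; inferred from the `t` column if omitted.
#' @export
read_trajectory_tsv <- function(path, dt = NULL) {
  df <- utils::read.delim(path)
  traj <- tibble::as_tibble(df)
  attr(traj, "dt") <- if (is.null(dt)) df$t[2] - df$t[1] else dt
  traj
}

#' Write direction events as a BIDS-style events TSV
#'
#' Columns `onset`, `duration` (seconds) and `trial_type` (the bin-center
#' label in degrees).
#'
#' @param events Event tibble from [extract_events()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$bin)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the tidy study results table as TSV
#'
#' Long-format table (one row per subject x condition) designed as direct
#' input for downstream mixed-model software.
#'
#' @param table Tidy results tibble from [run_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
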