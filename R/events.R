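#' Direction binning scheme
#'
#' Partitions the full 360-degree space of walking direction into equally
#' spaced, half-open bins. The default is six 60-degree bins with edges at
#' 0, 60, ..., 300 and center labels 30, 90, ..., 330.
#'
#' @param n_bins Number of bins (default 6).
#' @param bin_width Bin width in degrees; `n_bins * bin_width` must be 360.
#' @return An object of class `direction_binning` with `edges` and
#'   `centers`.
#' @export
direction_binning <- function(n_bins = 6L, bin_width = 360 / n_bins) {
  if (n_bins < 1 || abs(n_bins * bin_width - 360) > 1e-9) {
    stop("bins must tile the circle: n_bins * bin_width == 360")
  }
  edges <- seq(0, 360 - bin_width, by = bin_width)
  structure(list(n_bins = as.integer(n_bins), bin_width = bin_width,
                 edges = edges, centers = edges + bin_width / 2),
            class = "direction_binning")
}

#' Assign headings to direction bins
#'
#' Reduces headings modulo 360 and assigns each to its half-open bin
#' `[edge, edge + width)`; the returned label is the bin center, so 0
#' degrees maps to 30 and an exact edge (e.g. 60) belongs to the upper bin.
#'
#' @param heading Headings in degrees (any real values).
#' @param binning A [direction_binning()].
#' @return Bin-center labels in degrees, same length as `heading`.
#' @export
#' @examples
#' bin_direction(c(0, 60, 359.9), direction_binning()) # 30 90 330
bin_direction <- function(heading, binning = direction_binning()) {
  if (any(!is.finite(heading))) stop("headings must be finite")
  h <- heading %% 360
  h[h >= 360] <- 0   # guard against floating-point wrap
  binning$centers[floor(h / binning$bin_width) + 1L]
}

#' Extract consistent-walking direction events from a trajectory
#'
#' A direction event is a maximal run of consecutive trajectory samples that
#' share a direction bin and move at or above `min_speed` (standing still is
#' not walking); runs are kept only if they last at least `min_duration`
#' seconds. Event onset is the time of the first sample, duration is the
#' run length times the sampling step.
#'
#' @param traj A trajectory tibble (columns `t`, `heading`, `speed`).
#' @param binning A [direction_binning()].
#' @param min_duration Minimum event duration in seconds (default 1).
#' @param min_speed Minimum speed in vm/s to count as walking
#'   (default 0.05).
#' @return A tibble with columns `onset`, `duration`, `bin` (center label);
#'   zero rows for an empty or event-free trajectory.
#' @export
extract_events <- function(traj, binning = direction_binning(),
                           min_duration = 1, min_speed = 0.05) {
  if (nrow(traj) == 0) {
    return(tibble::tibble(onset = numeric(), duration = numeric(),
                          bin = numeric()))
  }
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- traj$t[2] - traj$t[1]
  bins <- bin_direction(traj$heading, binning)
  key <- ifelse(traj$speed >= min_speed, bins, NA_real_)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$lengths * dt >= min_duration
  tibble::tibble(onset = traj$t[starts[keep]],
                 duration = r$lengths[keep] * dt,
                 bin = r$values[keep])
}

#' Build classifier examples from direction events
#'
#' Maps each event to the fMRI volumes whose acquisition window overlaps the
#' event interval `[onset, onset + duration)`, shifts those volume indices
#' forward by `lag_TRs` volumes to adjust for hemodynamic lag (default two
#' TRs = 4.72 s at TR = 2.36 s), and averages the voxel patterns of all
#' covered volumes into a single example. Events whose shifted volumes fall
#' past the end of the run are dropped (counted in `n_dropped`).
#'
#' @param events Event tibble from [extract_events()].
#' @param run A `cleaned_run` (or `bold_run`) supplying `data` and `TR`.
#' @param TR Repetition time in seconds (default taken from `run`).
#' @param lag_TRs Hemodynamic lag in whole volumes (default 2).
#' @param binning The [direction_binning()] defining the label set.
#' @param session_id Optional session identifier carried through.
#' @return An object of class `example_set`: list with `X` (examples x
#'   voxels), `y` (factor of bin centers), `onsets`, `durations`,
#'   `class_counts`, `n_dropped`, `session_id`.
#' @export
events_to_examples <- function(events, run, TR = run$TR, lag_TRs = 2L,
                               binning = direction_binning(),
                               session_id = NA_character_) {
  n_vol <- nrow(run$data)
  rows <- vector("list", nrow(events))
  kept <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    first0 <- floor(events$onset[i] / TR)
    last0 <- ceiling((events$onset[i] + events$duration[i]) / TR) - 1
    vols <- (first0:last0) + lag_TRs + 1   # 1-based row indices after shift
    if (max(vols) > n_vol) next            # past run end: drop
    kept[i] <- TRUE
    rows[[i]] <- colMeans(run$data[vols, , drop = FALSE])
  }
  X <- do.call(rbind, rows[kept])
  if (is.null(X)) X <- matrix(numeric(), 0, ncol(run$data))
  y <- factor(events$bin[kept], levels = binning$centers)
  structure(list(X = X, y = y,
                 onsets = events$onset[kept],
                 durations = events$duration[kept],
                 class_counts = table(y),
                 n_dropped = sum(!kept),
                 session_id = session_id),
            class = "example_set")
}

#' Check the class distribution of an example set
#'
#' A session is usable for decoding only if every direction bin has at
#' least `min_per_class` examples and every temporal fold contains at least
#' one example of every bin (otherwise balanced training and per-fold
#' scoring are undefined). Sessions failing the check are excluded from
#' decoding, mirroring participant exclusion in under-sampled designs.
#'
#' @param es An `example_set`.
#' @param min_per_class Minimum examples per bin (default 3).
#' @param k_folds Number of temporal folds checked (default 3).
#' @return A list with `pass` (logical), `class_counts`, `fold_table`
#'   (fold x class counts), and `reason` (`NA` if passing).
#' @export
check_class_distribution <- function(es, min_per_class = 3L, k_folds = 3L) {
  n <- length(es$y)
  counts <- table(es$y)
  if (n < k_folds) {
    return(list(pass = FALSE, class_counts = counts, fold_table = NULL,
                reason = "fewer examples than folds"))
  }
  fold <- make_folds(es, k = k_folds)$fold
  fold_table <- table(factor(fold, levels = seq_len(k_folds)), es$y)
  pass <- all(counts >= min_per_class) && all(fold_table >= 1)
  reason <- if (pass) NA_character_
  else if (any(counts < min_per_class)) "bin below minimum example count"
  else "bin absent from a fold"
  list(pass = pass, class_counts = counts, fold_table = fold_table,
       reason = reason)
}
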