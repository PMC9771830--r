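# Shared fixtures, built in code at test time.

bin_centers <- direction_binning()$centers

# Construct an example_set directly from parts (bypasses the bold pipeline).
make_es <- function(X, y, onsets = seq_len(nrow(X)),
                    session_id = "test") {
  y <- factor(y, levels = bin_centers)
  structure(list(X = X, y = y, onsets = onsets,
                 durations = rep(1, nrow(X)),
                 class_counts = table(y), n_dropped = 0L,
                 session_id = session_id),
            class = "example_set")
}

# Six well-separated Gaussian clusters in 6-voxel space: voxel j is high
# for class j. Linearly separable when noise is small.
toy_example_set <- function(n_per_class = 6, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(bin_centers, each = n_per_class)
    n <- length(y)
    X <- matrix(rnorm(n * 6, 0, noise), n, 6)
    X[cbind(seq_len(n), rep(seq_len(6), each = n_per_class))] <-
      X[cbind(seq_len(n), rep(seq_len(6), each = n_per_class))] + 3
    # interleave classes in time so temporal folds all contain every class
    ord <- order(rep(seq_len(n_per_class), times = 6))
    make_es(X[ord, , drop = FALSE], y[ord])
  })
}

# Labels independent of the features: decoding must be at chance.
null_example_set <- function(n_per_class = 8, n_voxels = 8, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(bin_centers, each = n_per_class)
    ord <- order(rep(seq_len(n_per_class), times = 6))
    make_es(matrix(rnorm(length(y) * n_voxels), length(y), n_voxels),
            y[ord])
  })
}

# A small synthetic session: trajectory + tuned bold -> example set.
# Returns the full run_subject-style pieces without the pipeline wrapper.
quick_session <- function(seed, duration = 250, n_voxels = 12, gain = 0.5,
                          tuning_sd = 30, noise_sd = 1, fraction_tuned = 0.5,
                          dt = 0.1) {
  traj <- simulate_trajectory(duration = duration, dt = dt, seed = seed)
  spec <- voxel_tuning_spec(n_voxels = n_voxels, tuning_sd = tuning_sd,
                            gain = gain, noise_sd = noise_sd,
                            fraction_tuned = fraction_tuned)
  run <- generate_tuned_bold(traj, spec, seed = seed + 1)
  cleaned <- clean_signal(run)
  events <- extract_events(traj)
  es <- events_to_examples(events, cleaned)
  list(traj = traj, run = run, cleaned = cleaned, events = events, es = es)
}

# Independent brute-force oracle: balanced accuracy via explicit confusion
# matrix (mean of diagonal / row sums over observed classes).
oracle_balanced_accuracy <- function(y_true, y_pred) {
  lv <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  cm <- table(factor(as.character(y_true), levels = lv),
              factor(as.character(y_pred), levels = lv))
  present <- rowSums(cm) > 0
  mean(diag(cm)[present] / rowSums(cm)[present])
}

# Independent brute-force oracle: maximal run lengths over a sample-wise
# bin/valid sequence, by explicit scanning.
oracle_events <- function(bins, valid, dt, min_duration) {
  n <- length(bins)
  out <- list()
  i <- 1
  while (i <= n) {
    if (!valid[i]) { i <- i + 1; next }
    j <- i
    while (j < n && valid[j + 1] && bins[j + 1] == bins[i]) j <- j + 1
    len <- j - i + 1
    if (len * dt >= min_duration) {
      out[[length(out) + 1]] <- c(onset = (i - 1) * dt,
                                  duration = len * dt, bin = bins[i])
    }
    i <- j + 1
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      bin = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Uniform points on a disk by rejection sampling from the bounding square
# (independent of the package's square-root-radius sampler).
oracle_uniform_disk <- function(n, R) {
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- matrix(runif(2 * n, -R, R), ncol = 2)
    keep <- rowSums(cand^2) <= R^2
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}
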