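#' Circular-Gaussian direction-tuning response
#'
#' Response of a direction-tuned unit: directionally selective populations
#' respond to non-preferred directions in proportion to their circular
#' similarity to the preferred direction, following a Gaussian profile.
#'
#' @param heading Current walking direction in degrees.
#' @param preferred Preferred direction of the unit in degrees.
#' @param tuning_sd Tuning width sigma in degrees (> 0).
#' @return `exp(-delta^2 / (2 * tuning_sd^2))` in (0, 1], where `delta` is
#'   the signed circular difference mapped to (-180, 180]. Vectorized.
#' @export
#' @examples
#' tuning_response(90, 90, 30)        # 1
#' tuning_response(120, 90, 30)       # exp(-1/2)
tuning_response <- function(heading, preferred, tuning_sd) {
  if (any(tuning_sd <= 0)) stop("`tuning_sd` must be > 0")
  d <- circ_diff(heading, preferred)
  exp(-d^2 / (2 * tuning_sd^2))
}

#' Voxel population tuning specification
#'
#' Parameters of the synthetic direction-tuned voxel population. `gain`
#' scales the stimulus-driven response amplitude (the neural-gain knob that
#' stands in for dopaminergic/pharmacological modulation); `tuning_sd` is
#' the generative tuning width (broader widths emulate the dedifferentiated
#' tuning attributed to aging); `fraction_tuned` controls how many voxels
#' carry any direction signal at all.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param tuning_sd Generative circular-Gaussian tuning width, degrees (> 0).
#' @param gain Signal amplitude, arbitrary units (>= 0).
#' @param baseline Mean signal level, arbitrary units.
#' @param noise_sd Standard deviation of iid Gaussian voxel noise (>= 0).
#' @param fraction_tuned Proportion of voxels carrying direction signal,
#'   in \[0, 1\]. The first `round(fraction_tuned * n_voxels)` voxels are
#'   tuned (deterministic, for testability).
#' @param preferred_direction Optional vector of per-voxel preferred
#'   directions in degrees; by default drawn uniformly on \[0, 360) when the
#'   run is generated.
#' @return An object of class `voxel_tuning_spec`.
#' @export
voxel_tuning_spec <- function(n_voxels = 100, tuning_sd = 30, gain = 0.5,
                              baseline = 100, noise_sd = 2,
                              fraction_tuned = 0.5,
                              preferred_direction = NULL) {
  if (n_voxels < 1) stop("`n_voxels` must be >= 1")
  if (tuning_sd <= 0) stop("`tuning_sd` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (fraction_tuned < 0 || fraction_tuned > 1) {
    stop("`fraction_tuned` must be in [0, 1]")
  }
  if (!is.null(preferred_direction) &&
      length(preferred_direction) != n_voxels) {
    stop("`preferred_direction` must have one entry per voxel")
  }
  structure(list(n_voxels = as.integer(n_voxels), tuning_sd = tuning_sd,
                 gain = gain, baseline = baseline, noise_sd = noise_sd,
                 fraction_tuned = fraction_tuned,
                 preferred_direction = preferred_direction),
            class = "voxel_tuning_spec")
}

#' Generate a direction-tuned synthetic BOLD run
#'
#' Builds a volumes x voxels time series aligned to a trajectory. Volume `v`
#' of a tuned voxel is
#' `baseline + gain * mean(tuning_response)` over the trajectory samples
#' falling in the lag-shifted acquisition window
#' `[(v-1)*TR - lag, v*TR - lag)`, plus shared low-frequency drift and iid
#' Gaussian noise. Untuned voxels omit the gain term. The hemodynamic delay
#' is modelled as a pure temporal shift (default two TRs = 4.72 s), which is
#' exactly the correction the decoding stage applies; an optional canonical
#' double-gamma HRF convolution mode exists for robustness checks.
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param spec A [voxel_tuning_spec()].
#' @param TR Repetition time in seconds (default 2.36).
#' @param lag Hemodynamic delay in seconds (default `2 * TR` = 4.72).
#' @param drift_amplitude Amplitude of the shared low-frequency drift.
#' @param n_drift Number of cosine drift components.
#' @param seed Integer seed; identical seeds give identical runs.
#' @param ar_coef Optional AR(1) coefficient for temporally autocorrelated
#'   noise (default 0 = white).
#' @param hrf_convolve If `TRUE`, convolve the tuned signal with a canonical
#'   double-gamma HRF instead of (not in addition to) applying the shift;
#'   off by default.
#' @return An object of class `bold_run`: list with `data`
#'   (`n_volumes` x `n_voxels` matrix), `TR`, `n_volumes`, `confounds`
#'   (data frame of the generative drift components plus white sine
#'   regressors, fMRIPrep-style names), `preferred_direction`, `tuned`
#'   (logical per voxel), `lag`, `spec`.
#' @export
generate_tuned_bold <- function(traj, spec = voxel_tuning_spec(), TR = 2.36,
                                lag = 2 * TR, drift_amplitude = 1,
                                n_drift = 3, seed = 1L, ar_coef = 0,
                                hrf_convolve = FALSE) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- traj$t[2] - traj$t[1]
  duration <- nrow(traj) * dt
  if (duration < 2 * TR + lag) {
    stop("trajectory too short: need duration >= 2*TR + lag")
  }
  n_volumes <- as.integer(ceiling(duration / TR))
  p <- spec$n_voxels

  withr::with_seed(seed, {
    preferred <- spec$preferred_direction
    if (is.null(preferred)) preferred <- runif(p, 0, 360)
    n_tuned <- round(spec$fraction_tuned * p)
    tuned <- seq_len(p) <= n_tuned

    # per-volume mean tuning response, per voxel
    eff_lag <- if (hrf_convolve) 0 else lag
    vol_of_sample <- floor((traj$t + eff_lag) / TR) + 1L
    keep <- vol_of_sample >= 1L & vol_of_sample <= n_volumes
    sig <- matrix(0, n_volumes, p)
    if (n_tuned > 0 && any(keep)) {
      tr_mat <- tuning_response(
        matrix(traj$heading[keep], sum(keep), n_tuned),
        matrix(preferred[tuned], sum(keep), n_tuned, byrow = TRUE),
        spec$tuning_sd)
      counts <- tabulate(vol_of_sample[keep], nbins = n_volumes)
      sums <- rowsum(tr_mat, vol_of_sample[keep])
      nz <- as.integer(rownames(sums))
      sig[nz, tuned] <- sums / counts[nz]
      if (hrf_convolve) {
        h <- canonical_hrf(TR)
        sig <- apply(sig, 2, function(s) {
          stats::convolve(s, rev(h), type = "open")[seq_len(n_volumes)]
        })
      }
    }

    t_vol <- (seq_len(n_volumes) - 0.5) * TR
    periods <- runif(n_drift, 1.5 * 128, max(2 * duration, 400))
    phases <- runif(n_drift, 0, 2 * pi)
    drift_comp <- vapply(seq_len(n_drift), function(k) {
      cos(2 * pi * t_vol / periods[k] + phases[k])
    }, numeric(n_volumes))
    drift <- drift_amplitude * rowSums(drift_comp)

    noise <- matrix(rnorm(n_volumes * p, 0, spec$noise_sd), n_volumes, p)
    if (ar_coef != 0) {
      noise <- apply(noise, 2, function(e) {
        as.numeric(stats::filter(e, ar_coef, method = "recursive"))
      }) * sqrt(1 - ar_coef^2)
    }

    data <- spec$baseline + spec$gain * sig + drift + noise
    confounds <- as.data.frame(drift_comp)
    names(confounds) <- paste0("drift_", seq_len(n_drift))
    confounds[paste0("comp_", 1:2)] <- replicate(2, rnorm(n_volumes),
                                                 simplify = FALSE)

    structure(list(data = data, TR = TR, n_volumes = n_volumes,
                   confounds = confounds, preferred_direction = preferred,
                   tuned = tuned, lag = lag, spec = spec),
              class = "bold_run")
  })
}

# canonical double-gamma HRF sampled at TR (peak ~5 s, undershoot ~15 s)
canonical_hrf <- function(TR, length_s = 30) {
  t <- seq(0, length_s, by = TR)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / sum(h)
}

#' Clean a BOLD run for classification
#'
#' Applies, in fixed order, the standard signal-cleaning contract used
#' before pattern classification: per voxel (1) remove the linear trend,
#' (2) project out discrete-cosine high-pass basis functions with period
#' longer than `cutoff_s` (default 128 s, i.e. a 1/128 Hz cutoff),
#' (3) regress out up to `n_confounds_used` confound columns (OLS
#' residuals; collinear columns are dropped with a warning), and
#' (4) z-standardize. Voxels left with zero variance are flagged constant
#' and set to zero rather than producing non-finite values.
#'
#' @param run A `bold_run` (or any list with `data`, `TR`, `confounds`).
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @param n_confounds_used Maximum number of confound columns regressed out
#'   (default 10).
#' @return An object of class `cleaned_run`: list with `data` (z-scored
#'   volumes x voxels), `filter_cutoff` (Hz), `TR`, `n_volumes`,
#'   `constant_voxels` (indices flagged during z-scoring).
#' @export
clean_signal <- function(run, cutoff_s = 128, n_confounds_used = 10L) {
  Y <- run$data
  V <- nrow(Y)
  if (V < 3) stop("need at least 3 volumes to clean a run")

  residualize <- function(Y, X) {
    X <- cbind(1, X)
    Y - X %*% qr.coef(qr(X), Y)
  }

  # 1. linear detrend
  Y <- residualize(Y, seq_len(V))

  # 2. discrete-cosine high-pass: remove periods > cutoff_s
  K <- floor(2 * V * run$TR / cutoff_s)
  if (K >= 1) {
    v <- seq_len(V) - 0.5
    dct <- vapply(seq_len(K), function(k) cos(pi * k * v / V), numeric(V))
    Y <- residualize(Y, dct)
  }

  # 3. confound regression
  conf <- run$confounds
  if (!is.null(conf) && ncol(conf) > 0 && n_confounds_used > 0) {
    X <- as.matrix(conf[, seq_len(min(n_confounds_used, ncol(conf))),
                        drop = FALSE])
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) {
      keep <- sort(q$pivot[seq_len(q$rank)])
      keep <- setdiff(keep, 1) - 1   # drop intercept index, shift back
      warning("dropping ", ncol(X) - length(keep),
              " collinear confound column(s)")
      X <- X[, keep, drop = FALSE]
    }
    Y <- residualize(Y, X)
  }

  # 4. z-standardize
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  constant <- unname(which(sdv < 1e-10))
  sdv[constant] <- 1
  Y <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
  Y[, constant] <- 0
  if (length(constant)) {
    warning(length(constant), " voxel(s) constant after filtering; set to 0")
  }

  structure(list(data = Y, filter_cutoff = 1 / cutoff_s, TR = run$TR,
                 n_volumes = V, constant_voxels = constant),
            class = "cleaned_run")
}
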