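#' Circular-arena specification
#'
#' Describes the virtual circular arena: a grass plane bounded by a wall, in
#' which the participant navigates freely. Distances are measured in virtual
#' meters (vm); 1 vm corresponds to 62.5 Unreal engine units.
#'
#' @param radius_vm Arena radius in virtual meters (> 0).
#' @param unreal_units_per_vm Conversion factor to engine units (default 62.5).
#' @param cue_positions Optional n x 2 matrix of cue positions (cosmetic; not
#'   used by any computation).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(radius_vm = 25, unreal_units_per_vm = 62.5,
                       cue_positions = NULL) {
  check_positive_scalar(radius_vm = radius_vm,
                        unreal_units_per_vm = unreal_units_per_vm)
  structure(list(radius_vm = radius_vm,
                 unreal_units_per_vm = unreal_units_per_vm,
                 cue_positions = cue_positions),
            class = "arena_spec")
}

#' Object set for the spatial-memory task
#'
#' The task asks the participant to remember the locations of exactly five
#' objects placed strictly inside the arena disk.
#'
#' @param positions 5 x 2 numeric matrix of object coordinates (vm).
#' @param names Character vector of 5 object identifiers.
#' @param arena An [arena_spec()] used to validate that positions lie inside
#'   the arena.
#' @return An object of class `object_set`.
#' @export
object_set <- function(positions, names = paste0("object_", seq_len(nrow(positions))),
                       arena = arena_spec()) {
  positions <- as.matrix(positions)
  if (nrow(positions) != 5 || ncol(positions) != 2) {
    stop("an object set holds exactly 5 two-dimensional positions")
  }
  r <- sqrt(rowSums(positions^2))
  if (any(r >= arena$radius_vm)) {
    stop("all object positions must lie strictly inside the arena")
  }
  if (length(names) != 5) stop("need exactly 5 object names")
  structure(list(positions = positions, names = as.character(names)),
            class = "object_set")
}

#' Draw a random object set inside the arena
#'
#' Places 5 objects at area-uniform positions within an annulus of the arena
#' (by default between 20% and 80% of the radius, keeping objects away from
#' the wall and the starting position at the center).
#'
#' @param arena An [arena_spec()].
#' @param seed Integer seed.
#' @param min_frac,max_frac Radial placement range as fractions of the radius.
#' @return An `object_set`.
#' @export
random_object_set <- function(arena = arena_spec(), seed = 1L,
                              min_frac = 0.2, max_frac = 0.8) {
  withr::with_seed(seed, {
    u <- runif(5, min_frac^2, max_frac^2)
    r <- arena$radius_vm * sqrt(u)
    th <- runif(5, 0, 2 * pi)
    object_set(cbind(r * cos(th), r * sin(th)), arena = arena)
  })
}

#' Simulate a free-navigation trajectory
#'
#' Generates a smooth random walk of the walking direction inside the arena:
#' heading follows a wrapped Gaussian random walk with innovation standard
#' deviation `turn_volatility * sqrt(dt)` per step, position is integrated
#' from heading and (jittered) speed, and the agent is steered back toward
#' the arena center when it approaches the wall. Heading records the
#' direction of movement, in degrees counterclockwise from the positive
#' x-axis, wrapped to `[0, 360)`.
#'
#' @param arena An [arena_spec()].
#' @param duration Session duration in seconds (> 0).
#' @param dt Sampling step in seconds (default 0.1, i.e. 10 Hz).
#' @param turn_volatility Heading diffusion in degrees per sqrt(second).
#' @param mean_speed Mean walking speed in vm/s (>= 0).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param heading0 Initial heading in degrees (default: random).
#' @param speed_cv Coefficient of variation of the per-sample speed jitter
#'   (speeds are truncated at zero).
#' @param start Starting position, default the arena center, mirroring the
#'   task's center placement.
#' @return A tibble with columns `t`, `x`, `y`, `heading`, `speed` and
#'   attributes `dt` and `arena`; `length(t) = round(duration/dt)`.
#' @export
simulate_trajectory <- function(arena = arena_spec(), duration, dt = 0.1,
                                turn_volatility = 40, mean_speed = 2,
                                seed = 1L, heading0 = NULL, speed_cv = 0.2,
                                start = c(0, 0)) {
  check_positive_scalar(duration = duration, dt = dt)
  if (mean_speed < 0) stop("`mean_speed` must be >= 0")
  n <- round(duration / dt)
  if (n < 1) stop("duration/dt must give at least one sample")
  R <- arena$radius_vm
  wall <- 0.95 * R

  withr::with_seed(seed, {
    if (is.null(heading0)) heading0 <- runif(1, 0, 360)
    innov <- rnorm(n, 0, turn_volatility * sqrt(dt))
    speeds <- mean_speed * pmax(0, 1 + rnorm(n, 0, speed_cv))
    steer_noise <- rnorm(n, 0, 15)

    x <- y <- heading <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    h <- heading0
    for (i in seq_len(n)) {
      # wall avoidance: when a step would leave the safe disk, head back
      # toward the center (with a little noise) instead
      step <- speeds[i] * dt
      nx <- x[i] + step * cos(h * pi / 180)
      ny <- y[i] + step * sin(h * pi / 180)
      if (sqrt(nx^2 + ny^2) > wall && step > 0) {
        h <- (atan2(-y[i], -x[i]) * 180 / pi + steer_noise[i]) %% 360
        nx <- x[i] + step * cos(h * pi / 180)
        ny <- y[i] + step * sin(h * pi / 180)
        rr <- sqrt(nx^2 + ny^2)
        if (rr > wall) { nx <- nx * wall / rr; ny <- ny * wall / rr }
      }
      heading[i] <- h %% 360
      if (i < n) { x[i + 1] <- nx; y[i + 1] <- ny }
      h <- h + innov[i]
    }

    traj <- tibble::tibble(t = (seq_len(n) - 1) * dt, x = x, y = y,
                           heading = heading, speed = speeds)
    attr(traj, "dt") <- dt
    attr(traj, "arena") <- arena
    traj
  })
}

#' Simulate the feedback phase of the spatial-memory task
#'
#' Each repetition presents all five objects in pseudo-random order; the
#' simulated response is the true location plus isotropic Gaussian memory
#' noise whose standard deviation decays geometrically across repetitions
#' (learning), clipped to the arena. Responses can be omitted with a
#' configurable probability, emulating trials lost to the response time
#' limit.
#'
#' @param arena An [arena_spec()].
#' @param objects An [object_set()].
#' @param memory_noise_sd Initial response noise sd in vm (>= 0).
#' @param n_repetitions Number of repetitions of the 5-object block
#'   (default 6, giving 5 x 6 = 30 feedback trials).
#' @param noise_decay Multiplicative decay of the noise sd per repetition
#'   (in (0, 1] for learning).
#' @param omission_prob Per-response probability of a missing response.
#' @param seed Integer seed.
#' @return A tibble with one row per object presentation (5 x n_repetitions
#'   rows): `trial`, `presentation`, `object`, `true_x`, `true_y`,
#'   `resp_x`, `resp_y` (NA when omitted), `rt` (s).
#' @export
simulate_feedback_phase <- function(arena = arena_spec(),
                                    objects = random_object_set(arena),
                                    memory_noise_sd = 8, n_repetitions = 6,
                                    noise_decay = 0.75, omission_prob = 0,
                                    seed = 1L) {
  if (n_repetitions < 1) stop("`n_repetitions` must be >= 1")
  if (memory_noise_sd < 0) stop("`memory_noise_sd` must be >= 0")
  R <- arena$radius_vm
  withr::with_seed(seed, {
    rows <- vector("list", n_repetitions)
    for (k in seq_len(n_repetitions)) {
      ord <- sample.int(5)
      sd_k <- memory_noise_sd * noise_decay^(k - 1)
      true <- objects$positions[ord, , drop = FALSE]
      resp <- true + matrix(rnorm(10, 0, sd_k), 5, 2)
      # clip responses to the arena disk
      rr <- sqrt(rowSums(resp^2))
      out <- rr > R
      if (any(out)) resp[out, ] <- resp[out, ] * (0.999 * R / rr[out])
      omit <- runif(5) < omission_prob
      resp[omit, ] <- NA_real_
      rows[[k]] <- tibble::tibble(
        trial = k, presentation = seq_len(5),
        object = objects$names[ord],
        true_x = true[, 1], true_y = true[, 2],
        resp_x = resp[, 1], resp_y = resp[, 2],
        rt = pmin(5 + rexp(5, 1 / 10), 60))
    }
    do.call(rbind, rows)
  })
}

#' Euclidean distance error between response and true location
#'
#' @param response,true_location Numeric vectors of length 2, or n x 2
#'   matrices (rows paired).
#' @return Nonnegative distance(s) in vm.
#' @export
#' @examples
#' distance_error(c(0, 0), c(3, 4)) # 5
distance_error <- function(response, true_location) {
  r <- rbind(response); tl <- rbind(true_location)
  if (ncol(r) != 2 || ncol(tl) != 2) stop("points must be 2-D")
  unname(sqrt(rowSums((r - tl)^2)))
}

#' Mean distance error of one feedback trial
#'
#' Averages per-object distance errors over the non-missing responses of a
#' trial. A trial with no responses at all yields `NA` (flagged missing),
#' never zero.
#'
#' @param errors Numeric vector of per-object distance errors, `NA` for
#'   missing responses.
#' @return The mean over non-missing errors, or `NA_real_` if all missing.
#' @export
trial_error <- function(errors) {
  if (all(is.na(errors))) return(NA_real_)
  mean(errors, na.rm = TRUE)
}

#' Per-trial behavioural summary
#'
#' Computes, for each feedback trial, the mean distance error over
#' non-missing responses and its natural-log transform (the scale on which
#' learning is measured).
#'
#' @param feedback A feedback tibble from [simulate_feedback_phase()].
#' @return A tibble with columns `trial`, `n_responses`, `mean_error`,
#'   `log_error`.
#' @export
behavior_summary <- function(feedback) {
  err <- distance_error(cbind(feedback$resp_x, feedback$resp_y),
                        cbind(feedback$true_x, feedback$true_y))
  trials <- sort(unique(feedback$trial))
  me <- vapply(trials, function(k) trial_error(err[feedback$trial == k]),
               numeric(1))
  nr <- vapply(trials, function(k) sum(!is.na(err[feedback$trial == k])),
               numeric(1))
  tibble::tibble(trial = trials, n_responses = as.integer(nr),
                 mean_error = me,
                 log_error = ifelse(me > 0, log(me), NA_real_))
}

#' First-minus-last learning change on the log scale
#'
#' `log(first-trial error) - log(last-trial error)`; positive values mean
#' improvement across the feedback phase. Errors of zero (or missing trials)
#' are rejected since the log is undefined — no offset is added.
#'
#' @param behavior A tibble from [behavior_summary()].
#' @return A single number (log-vm difference).
#' @export
learning_change <- function(behavior) {
  first <- behavior$mean_error[which.min(behavior$trial)]
  last <- behavior$mean_error[which.max(behavior$trial)]
  if (is.na(first) || is.na(last) || first <= 0 || last <= 0) {
    stop("learning change needs positive, non-missing first and last trial errors")
  }
  log(first) - log(last)
}

#' Area-uniform samples from the arena disk
#'
#' Samples points uniformly over the area of a disk of radius `R` using the
#' square-root radius transform (naive radius-uniform sampling would
#' concentrate points near the center and bias chance statistics).
#'
#' @param n Number of points.
#' @param R Disk radius.
#' @return An n x 2 matrix of coordinates.
#' @export
sample_uniform_disk <- function(n, R) {
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Monte-Carlo chance distribution of group-mean distance errors
#'
#' Simulates random task performance: a pool of locations is sampled
#' area-uniformly within the arena, the task is then simulated `n_sims`
#' times with every (non-missing) response of every participant replaced by
#' a random draw from the pool, and the group-mean distance error is
#' recorded per trial. The result is the chance distribution against which
#' observed trial-specific group means are compared.
#'
#' @param arena An [arena_spec()].
#' @param participants A list of feedback tibbles (one per participant), as
#'   returned by [simulate_feedback_phase()].
#' @param n_locations Size of the uniform location pool (default 1e5).
#' @param n_sims Number of simulated task runs (default 1000).
#' @param seed Integer seed.
#' @return An `n_sims` x `n_trials` matrix of group-mean distance errors;
#'   column j is the chance distribution for trial j.
#' @export
chance_distribution <- function(arena, participants, n_locations = 100000L,
                                n_sims = 1000L, seed = 1L) {
  if (n_locations < 1 || n_sims < 1) stop("n_locations and n_sims must be >= 1")
  recs <- do.call(rbind, lapply(seq_along(participants), function(p) {
    fb <- participants[[p]]
    keep <- !is.na(fb$resp_x)
    data.frame(participant = p, trial = fb$trial[keep],
               true_x = fb$true_x[keep], true_y = fb$true_y[keep])
  }))
  trials <- sort(unique(recs$trial))
  withr::with_seed(seed, {
    pool <- sample_uniform_disk(n_locations, arena$radius_vm)
    out <- matrix(NA_real_, n_sims, length(trials),
                  dimnames = list(NULL, paste0("trial_", trials)))
    pt <- interaction(recs$participant, recs$trial, drop = TRUE)
    trial_of_pt <- as.numeric(tapply(recs$trial, pt, function(v) v[1]))
    for (s in seq_len(n_sims)) {
      idx <- sample.int(n_locations, nrow(recs), replace = TRUE)
      err <- sqrt((pool[idx, 1] - recs$true_x)^2 +
                  (pool[idx, 2] - recs$true_y)^2)
      pt_mean <- tapply(err, pt, mean)           # participant x trial mean
      out[s, ] <- tapply(pt_mean, trial_of_pt, mean)[as.character(trials)]
    }
    out
  })
}
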