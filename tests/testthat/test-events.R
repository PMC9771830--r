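test_that("direction binning tiles the circle with half-open 60-degree bins", {
  b <- direction_binning()
  expect_equal(b$n_bins * b$bin_width, 360)
  expect_equal(b$centers, c(30, 90, 150, 210, 270, 330))
  expect_equal(bin_direction(0, b), 30)
  expect_equal(bin_direction(60, b), 90)    # edge belongs to the upper bin
  expect_equal(bin_direction(359.9, b), 330)
  expect_equal(bin_direction(-30, b), 330)  # wraps below zero
  expect_error(direction_binning(5, 60), "tile")
})

test_that("bin assignment is total and periodic", {
  b <- direction_binning()
  withr::with_seed(1, h <- runif(500, -720, 720))
  expect_equal(bin_direction(h, b), bin_direction(h + 360, b))
  expect_true(all(bin_direction(h, b) %in% b$centers))
})

test_that("event extraction finds maximal consistent-walking runs", {
  dt <- 0.1
  mk_traj <- function(heading, speed = rep(1, length(heading))) {
    tr <- tibble::tibble(t = (seq_along(heading) - 1) * dt, x = 0, y = 0,
                         heading = heading, speed = speed)
    attr(tr, "dt") <- dt
    tr
  }
  # constant heading for 10 s: one event covering everything
  ev <- extract_events(mk_traj(rep(45, 100)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$bin, 30)
  expect_equal(ev$duration, 10)
  expect_equal(ev$onset, 0)
  # alternating bins every 0.5 s: all runs below the 1 s threshold
  ev <- extract_events(mk_traj(rep(c(rep(45, 5), rep(100, 5)), 10)))
  expect_equal(nrow(ev), 0)
  # runs of 0.9 s, 1.0 s and 3.7 s in one bin -> 2 events
  h <- c(rep(30, 9), rep(100, 12), rep(30, 10), rep(100, 12), rep(30, 37))
  ev <- extract_events(mk_traj(h))
  expect_equal(sum(ev$bin == 30), 2)
  expect_equal(sort(ev$duration[ev$bin == 30]), c(1.0, 3.7))
  # standing still is not walking
  ev <- extract_events(mk_traj(rep(45, 100), speed = rep(0.01, 100)))
  expect_equal(nrow(ev), 0)
  # empty trajectory -> empty event list
  expect_equal(nrow(extract_events(mk_traj(numeric(0)))), 0)
})

test_that("event extraction matches a brute-force run-length oracle", {
  dt <- 0.1
  b <- direction_binning()
  withr::with_seed(21, {
    for (case in 1:50) {
      n <- sample(30:150, 1)
      heading <- b$centers[sample.int(6, n, replace = TRUE)] +
        runif(n, -29, 29)
      speed <- ifelse(runif(n) < 0.15, 0, 1)
      tr <- tibble::tibble(t = (seq_len(n) - 1) * dt, x = 0, y = 0,
                           heading = heading, speed = speed)
      attr(tr, "dt") <- dt
      got <- extract_events(tr)
      want <- oracle_events(bin_direction(heading, b), speed >= 0.05, dt, 1)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0) {
        expect_equal(got$onset, want$onset)
        expect_equal(got$duration, want$duration)
        expect_equal(got$bin, want$bin)
      }
    }
  })
})

test_that("events partition trajectory time", {
  traj <- simulate_trajectory(duration = 200, seed = 17)
  ev <- extract_events(traj)
  expect_lte(sum(ev$duration), 200)
  # disjointness: each event ends before the next begins
  if (nrow(ev) > 1) {
    expect_true(all(ev$onset[-1] >= ev$onset[-nrow(ev)] +
                      ev$duration[-nrow(ev)] - 1e-9))
  }
})

test_that("examples average the lag-shifted covered volumes", {
  TR <- 2.36
  V <- 30
  run <- list(data = matrix(rep(seq_len(V), 4), V, 4), TR = TR) # row v = v
  # event of half a TR inside volume 5 (rows are 1-based): shifted by 2
  ev <- tibble::tibble(onset = 4.2 * TR, duration = 0.5 * TR, bin = 30)
  es <- events_to_examples(ev, run, TR = TR, lag_TRs = 2)
  expect_equal(unname(es$X[1, 1]), 7)          # volume 5 + lag 2
  # the lag offset in seconds is exactly 2 TRs = 4.72 s
  expect_equal(2 * TR, 4.72)
  # event spanning three volumes: pattern = mean of the three shifted rows
  ev <- tibble::tibble(onset = 10.2 * TR, duration = 2.3 * TR, bin = 90)
  es <- events_to_examples(ev, run, TR = TR, lag_TRs = 2)
  expect_equal(unname(es$X[1, 1]), mean(c(13, 14, 15)))
  # identical volumes with value v produce exactly v
  run2 <- list(data = matrix(6.5, V, 4), TR = TR)
  es <- events_to_examples(ev, run2, TR = TR, lag_TRs = 2)
  expect_equal(unname(es$X[1, 1]), 6.5)
})

test_that("events past the run end are dropped and counted", {
  TR <- 2.36
  run <- list(data = matrix(0, 10, 3), TR = TR)
  ev <- tibble::tibble(onset = c(2 * TR, 8.5 * TR), duration = c(TR, TR),
                       bin = c(30, 90))
  es <- events_to_examples(ev, run, TR = TR, lag_TRs = 2)
  expect_equal(length(es$y), 1)
  expect_equal(es$n_dropped, 1L)
  expect_equal(as.numeric(as.character(es$y)), 30)
})

test_that("class-distribution check enforces counts and per-fold coverage", {
  # balanced and interleaved: pass
  es <- toy_example_set(n_per_class = 10)
  chk <- check_class_distribution(es, min_per_class = 3, k_folds = 3)
  expect_true(chk$pass)
  # a bin with zero examples: fail
  X <- matrix(rnorm(50 * 4), 50, 4)
  es0 <- make_es(X, rep(c(30, 90, 150, 210, 270), each = 10))
  expect_false(check_class_distribution(es0)$pass)
  # counts fine overall but bin 30 absent from the last temporal third
  y <- c(rep(c(30, 90, 150, 210, 270, 330), times = 4),
         rep(c(90, 150, 210, 270, 330), times = 4))
  es3 <- make_es(matrix(rnorm(length(y) * 4), length(y), 4), y)
  chk3 <- check_class_distribution(es3, min_per_class = 3, k_folds = 3)
  expect_false(chk3$pass)
  expect_match(chk3$reason, "fold")
  # direct enumeration: bin 30 really is absent from fold 3
  n <- length(y)
  fold3 <- y[(n - n %/% 3 + 1):n]
  expect_false(30 %in% fold3)
})

test_that("round trip: sharply tuned noiseless voxels give label-consistent argmax patterns", {
  traj <- simulate_trajectory(duration = 250, seed = 31, turn_volatility = 30)
  pref <- direction_binning()$centers
  spec <- voxel_tuning_spec(n_voxels = 6, tuning_sd = 8, gain = 1,
                            baseline = 0, noise_sd = 0, fraction_tuned = 1,
                            preferred_direction = pref)
  run <- generate_tuned_bold(traj, spec, drift_amplitude = 0, seed = 1)
  ev <- extract_events(traj)
  es <- events_to_examples(ev, run)
  agree <- pref[max.col(es$X)] == as.numeric(as.character(es$y))
  # events are heading-consistent, so the argmax voxel recovers the label;
  # short events whose covered volumes straddle direction changes dilute
  # the pattern, so the strict check applies to events of >= 3 s
  long <- es$durations >= 3
  expect_gt(sum(long), 5)
  expect_gt(mean(agree[long]), 0.9)
  expect_gt(mean(agree), 3 / 6)   # overall still far above chance
})

test_that("events export as BIDS-style TSV", {
  ev <- tibble::tibble(onset = c(0, 2.5), duration = c(1.2, 3), bin = c(30, 270))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("onset", "duration", "trial_type"))
  expect_equal(back$trial_type, c(30, 270))
})
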