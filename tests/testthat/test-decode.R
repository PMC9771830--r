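test_that("folds are contiguous temporal thirds with remainder to the earliest", {
  es9 <- make_es(matrix(0, 9, 2), rep(bin_centers, length.out = 9),
                 onsets = 1:9)
  f <- make_folds(es9)
  expect_equal(f$fold, rep(1:3, each = 3))
  es10 <- make_es(matrix(0, 10, 2), rep(bin_centers, length.out = 10),
                  onsets = 1:10)
  f <- make_folds(es10)
  expect_equal(as.numeric(table(f$fold)), c(4, 3, 3))
  expect_equal(f$fold, rep(1:3, times = c(4, 3, 3)))
  # shuffled input rows: assignment follows onsets, not row order
  perm <- c(3, 1, 4, 10, 2, 6, 5, 9, 7, 8)
  es_sh <- make_es(matrix(0, 10, 2),
                   rep(bin_centers, length.out = 10)[perm],
                   onsets = (1:10)[perm])
  f_sh <- make_folds(es_sh)
  expect_equal(f_sh$fold, f$fold[perm])
  expect_error(make_folds(make_es(matrix(0, 2, 2), c(30, 90), onsets = 1:2)),
               "at least")
})

test_that("upsampling balances classes, keeps originals, and is seeded", {
  X <- matrix(seq_len(22 * 2), 22, 2)
  y <- factor(rep(bin_centers, times = c(4, 2, 4, 4, 4, 4)),
              levels = bin_centers)
  bal <- upsample_to_balance(X, y, seed = 3)
  expect_equal(as.numeric(table(bal$y)), rep(4, 6))
  expect_equal(bal$X[1:22, ], X)                   # originals retained
  expect_equal(nrow(bal$X), 24)
  dup <- bal$X[23:24, ]
  expect_true(all(dup[, 1] %in% X[y == "90", 1]))  # duplicates from class 90
  # already balanced: unchanged
  yb <- factor(rep(bin_centers, each = 3), levels = bin_centers)
  Xb <- matrix(0, 18, 2)
  expect_identical(upsample_to_balance(Xb, yb, seed = 1)$X, Xb)
  # identical seed, identical resample
  expect_identical(upsample_to_balance(X, y, seed = 3),
                   upsample_to_balance(X, y, seed = 3))
  expect_error(upsample_to_balance(X[1:4, ], factor(rep(30, 4),
                                                    levels = bin_centers)),
               NA) # single present class after droplevels is fine
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c(30, 90, 150), c(30, 90, 150)), 1)
  expect_equal(balanced_accuracy(c("A", "A", "B", "B"),
                                 c("A", "A", "A", "A")), 0.5)
  expect_error(balanced_accuracy(character(0), character(0)), "non-empty")
  withr::with_seed(7, {
    for (i in 1:50) {
      yt <- sample(bin_centers, 60, replace = TRUE)
      yp <- sample(bin_centers, 60, replace = TRUE)
      expect_equal(balanced_accuracy(yt, yp),
                   oracle_balanced_accuracy(yt, yp))
    }
  })
})

test_that("separable clusters decode perfectly; probabilities are calibrated rows", {
  es <- toy_example_set(n_per_class = 8, noise = 0.05)
  dec <- cross_validate(es, seed = 1)
  expect_equal(dec$balanced_accuracy, 1)
  expect_equal(unname(rowSums(dec$prob)), rep(1, 48), tolerance = 1e-9)
  expect_equal(as.character(dec$y_pred),
               colnames(dec$prob)[max.col(dec$prob)])
  expect_equal(length(dec$per_fold), 3)
  # a single informative voxel survives many noise voxels
  withr::with_seed(2, {
    y <- rep(bin_centers, each = 8)
    ord <- order(rep(1:8, times = 6))
    X <- cbind(match(y, bin_centers)[ord] * 2,
               matrix(rnorm(48 * 49, 0, 0.1), 48, 49))
    es1 <- make_es(X, y[ord])
  })
  expect_equal(cross_validate(es1, seed = 1)$balanced_accuracy, 1)
})

test_that("pure-noise decoding sits at the 1/6 chance level", {
  accs <- vapply(1:100, function(s) {
    cross_validate(null_example_set(n_per_class = 8, n_voxels = 8, seed = s),
                   seed = s)$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 6), 0.01)
})

test_that("held-out labels never influence training (no leakage)", {
  es <- quick_session(seed = 101)$es
  folds <- make_folds(es)
  dec1 <- cross_validate(es, folds = folds, seed = 9)
  es2 <- es
  i3 <- which(folds$fold == 3)
  withr::with_seed(1, es2$y[i3] <- sample(es2$y[i3]))  # corrupt fold 3 only
  dec2 <- cross_validate(es2, folds = folds, seed = 9)
  expect_equal(dec1$prob[i3, ], dec2$prob[i3, ])
  # train/test rows disjoint by construction
  for (f in 1:3) {
    expect_length(intersect(which(folds$fold == f),
                            which(folds$fold != f)), 0)
  }
})

test_that("permutation null is seeded, bounded, and centred near chance", {
  es <- null_example_set(n_per_class = 6, n_voxels = 6, seed = 3)
  pn1 <- permutation_null(es, n_iterations = 60, seed = 4)
  pn2 <- permutation_null(es, n_iterations = 60, seed = 4)
  expect_identical(pn1$scores, pn2$scores)
  expect_length(pn1$scores, 60)
  expect_true(all(pn1$scores >= 0 & pn1$scores <= 1))
  # the observed score of untuned data is a typical draw from its own null
  obs <- cross_validate(es, seed = 1)$balanced_accuracy
  expect_gte(obs, quantile(pn1$scores, 0.025) - 1e-9)
  expect_lte(obs, quantile(pn1$scores, 0.975) + 1e-9)
})

test_that("group null of means averages iteration-wise across subjects", {
  n1 <- structure(list(scores = rep(0.1, 5), n_iterations = 5L, seed = 1),
                  class = "permutation_null")
  n2 <- structure(list(scores = rep(0.2, 5), n_iterations = 5L, seed = 2),
                  class = "permutation_null")
  expect_equal(group_null_of_means(list(n1, n2)), rep(0.15, 5))
  expect_equal(group_null_of_means(list(n1)), n1$scores)
  n3 <- structure(list(scores = rep(0.2, 4), n_iterations = 4L, seed = 2),
                  class = "permutation_null")
  expect_error(group_null_of_means(list(n1, n3)), "same number")
  # variance shrinks as 1/m across independent subjects
  withr::with_seed(11, {
    nulls <- lapply(1:16, function(i) {
      structure(list(scores = rnorm(2000, 1 / 6, 0.05),
                     n_iterations = 2000L, seed = i),
                class = "permutation_null")
    })
    gsd <- sd(group_null_of_means(nulls))
    expect_equal(gsd, 0.05 / sqrt(16), tolerance = 0.1)
  })
})

test_that("higher gain never hurts decoding on average", {
  gains <- c(0.2, 0.6, 1.2)
  means <- vapply(gains, function(g) {
    mean(vapply(1:12, function(s) {
      ses <- quick_session(seed = 3000 + s, gain = g, n_voxels = 24,
                           fraction_tuned = 1)
      cross_validate(ses$es, seed = s)$balanced_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
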