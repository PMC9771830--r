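#' Multinomial logistic-regression classifier settings
#'
#' L2-regularized multinomial logistic regression in the sklearn-style
#' `C` parameterisation: the fit minimizes the summed multinomial
#' cross-entropy plus `1/(2C)` times the squared coefficient norm
#' (intercepts unpenalized). Internally this maps onto a single-lambda
#' ridge fit with `lambda = 1 / (C * n_train)`.
#'
#' @param C Inverse regularization strength (> 0, default 1).
#' @param tolerance Convergence tolerance (default 1e-4).
#' @param max_iterations Maximum solver iterations (default 1000).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(C = 1, tolerance = 1e-4, max_iterations = 1000L) {
  check_positive_scalar(C = C, tolerance = tolerance,
                        max_iterations = max_iterations)
  structure(list(C = C, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "classifier_spec")
}

#' Assign examples to temporal cross-validation folds
#'
#' Splits a session into `k` contiguous temporal thirds (examples ordered
#' by onset; remainders go to the earliest folds). Contiguous folds keep
#' temporally autocorrelated examples out of each other's training sets.
#' Deterministic: shuffling the input row order does not change the
#' assignment.
#'
#' @param es An `example_set`.
#' @param k Number of folds (default 3).
#' @return An object of class `fold_assignment` with `k` and `fold` (fold
#'   index per example, aligned with the rows of `es$X`).
#' @export
make_folds <- function(es, k = 3L) {
  n <- length(es$y)
  if (n < k) stop("need at least k examples to build k folds")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  fold[order(es$onsets)] <- rep(seq_len(k), times = sizes)
  structure(list(k = as.integer(k), fold = fold), class = "fold_assignment")
}

#' Upsample training examples to balance classes
#'
#' Duplicates rows of underrepresented classes (sampling with replacement,
#' seeded) until every class matches the largest class count. Original rows
#' are always retained; already balanced input is returned unchanged.
#'
#' @param X Training matrix (examples x voxels).
#' @param y Training labels (factor; every level must be present).
#' @param seed Integer seed for the resampling.
#' @return A list with balanced `X` and `y`.
#' @export
upsample_to_balance <- function(X, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  counts <- table(y)
  if (any(counts == 0)) stop("every class must be present in the training set")
  m <- max(counts)
  if (all(counts == m)) return(list(X = X, y = y))
  withr::with_seed(seed, {
    extra <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      need <- m - length(idx)
      if (need > 0) sample(idx, need, replace = TRUE) else integer(0)
    }))
    list(X = rbind(X, X[extra, , drop = FALSE]),
         y = factor(c(as.character(y), as.character(y)[extra]),
                    levels = levels(y)))
  })
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall over the classes present in
#' `y_true`; insensitive to class imbalance in the test set. Chance level
#' for `k` equally likely classes is `1/k` (16.66% for six direction bins).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return A score in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must be non-empty and of equal length")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  mean(vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1)))
}

# Fit L2 multinomial logistic regression (glmnet ridge, single lambda) and
# return class probabilities for `newx` via softmax on extracted
# coefficients (identical to predict.glmnet but much faster per call).
# glmnet's small-class-count advisory warning is muffled: balanced
# upsampled training sets routinely have < 8 examples per class by design.
fit_predict_multinom <- function(X, y, newx, spec) {
  lambda <- 1 / (spec$C * nrow(X))
  # a short decreasing path ending at the target lambda: warm starts make
  # the ridge solver converge where a cold single-lambda fit can stall
  path <- lambda * c(64, 8, 1)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "multinomial", alpha = 0, lambda = path,
                   standardize = FALSE, thresh = spec$tolerance,
                   maxit = spec$max_iterations),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  k <- length(fit$lambda)   # on non-convergence the last fitted entry is used
  B <- vapply(fit$beta, function(b) as.numeric(b[, k]), numeric(ncol(X)))
  eta <- sweep(newx %*% B, 2, as.numeric(fit$a0[, k]), "+")
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  prob <- ex / rowSums(ex)
  colnames(prob) <- fit$classnames
  prob
}

#' Within-session cross-validated decoding of walking direction
#'
#' For each fold, trains the multinomial classifier on the remaining folds
#' (after seeded upsampling to class balance), predicts the held-out fold,
#' and collects the six-class probability estimates. The headline balanced
#' accuracy is computed on the concatenated held-out predictions pooled
#' across folds; per-fold scores are reported as a secondary diagnostic.
#'
#' @param es An `example_set` (should have passed
#'   [check_class_distribution()]).
#' @param spec A [classifier_spec()].
#' @param folds A [make_folds()] assignment.
#' @param seed Integer seed (drives the per-fold upsampling).
#' @return An object of class `decoding_result`: `balanced_accuracy`
#'   (pooled), `per_fold`, `prob` (examples x 6, rows aligned with `es`),
#'   `y_true`, `y_pred`, `folds`.
#' @export
cross_validate <- function(es, spec = classifier_spec(),
                           folds = make_folds(es), seed = 1L) {
  classes <- levels(es$y)
  n <- length(es$y)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(NULL, classes))
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    bal <- upsample_to_balance(es$X[!test, , drop = FALSE], es$y[!test],
                               seed = seed + f)
    pr <- fit_predict_multinom(bal$X, bal$y, es$X[test, , drop = FALSE],
                               spec)
    prob[test, colnames(pr)] <- pr
  }
  y_pred <- factor(classes[max.col(prob, ties.method = "first")],
                   levels = classes)
  per_fold <- vapply(seq_len(folds$k), function(f) {
    balanced_accuracy(es$y[folds$fold == f], y_pred[folds$fold == f])
  }, numeric(1))
  structure(list(balanced_accuracy = balanced_accuracy(es$y, y_pred),
                 per_fold = per_fold, prob = prob,
                 y_true = es$y, y_pred = y_pred, folds = folds),
            class = "decoding_result")
}

#' Permutation null distribution of balanced accuracy
#'
#' Repeats the full cross-validation procedure with the training labels of
#' every fold independently permuted (test labels untouched — they define
#' the scoring), yielding the chance distribution of the pooled balanced
#' accuracy for one session.
#'
#' @param es An `example_set`.
#' @param spec A [classifier_spec()].
#' @param folds A [make_folds()] assignment.
#' @param n_iterations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `permutation_null` with `scores`
#'   (`n_iterations` balanced accuracies), `n_iterations`, `seed`.
#' @export
permutation_null <- function(es, spec = classifier_spec(),
                             folds = make_folds(es), n_iterations = 1000L,
                             seed = 1L) {
  classes <- levels(es$y)
  n <- length(es$y)
  train_sets <- lapply(seq_len(folds$k), function(f) {
    list(X = es$X[folds$fold != f, , drop = FALSE],
         y = es$y[folds$fold != f],
         test = which(folds$fold == f))
  })
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      y_pred <- character(n)
      for (f in seq_len(folds$k)) {
        ts <- train_sets[[f]]
        perm_y <- ts$y[sample.int(length(ts$y))]
        bal <- upsample_to_balance(ts$X, perm_y,
                                   seed = sample.int(2^30, 1))
        pr <- fit_predict_multinom(bal$X, bal$y,
                                   es$X[ts$test, , drop = FALSE], spec)
        y_pred[ts$test] <- colnames(pr)[max.col(pr, ties.method = "first")]
      }
      balanced_accuracy(as.character(es$y), y_pred)
    }, numeric(1))
  })
  structure(list(scores = scores, n_iterations = as.integer(n_iterations),
                 seed = seed),
            class = "permutation_null")
}

#' Group-level permutation null of sample means
#'
#' Combines per-subject permutation nulls into a null distribution of the
#' group mean by averaging across subjects within each iteration — the same
#' averaging applied to the observed per-subject scores.
#'
#' @param per_subject_nulls A list of `permutation_null` objects with equal
#'   `n_iterations`.
#' @return A numeric vector of group-mean scores (one per iteration).
#' @export
group_null_of_means <- function(per_subject_nulls) {
  ns <- vapply(per_subject_nulls, function(x) length(x$scores), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all subjects must have the same number of permutation iterations")
  }
  rowMeans(vapply(per_subject_nulls, function(x) x$scores,
                  numeric(ns[1])))
}
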