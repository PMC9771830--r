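#' One-sided one-sample t-test against chance
#'
#' Tests whether per-subject balanced accuracies exceed the chance baseline
#' (1/6 = 16.66% for six classes), alternative "greater". Zero-variance
#' input (all scores identical) is flagged and resolved by sign convention:
#' p = 0 if the common score is above chance, 1 if below, 0.5 at chance.
#'
#' @param scores Per-subject accuracy scores (n >= 2).
#' @param chance Chance level (default 1/6).
#' @return A tibble with `statistic`, `df`, `p_one_sided`, `p_adjusted`
#'   (NA until corrected), `method`, `flag`.
#' @export
t_test_vs_chance <- function(scores, chance = 1 / 6) {
  n <- length(scores)
  if (n < 2) stop("need at least 2 scores")
  if (stats::sd(scores) < 1e-12) {
    m <- mean(scores)
    p <- if (m > chance) 0 else if (m < chance) 1 else 0.5
    return(tibble::tibble(statistic = if (m == chance) 0 else sign(m - chance) * Inf,
                          df = n - 1, p_one_sided = p, p_adjusted = NA_real_,
                          method = "t-test", flag = "zero variance"))
  }
  tt <- stats::t.test(scores, mu = chance, alternative = "greater")
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_one_sided = tt$p.value, p_adjusted = NA_real_,
                 method = "t-test", flag = NA_character_)
}

#' One-sided permutation p-value
#'
#' Compares an observed group-mean score to its permutation null with the
#' add-one estimator `p = (1 + #[null >= observed]) / (1 + n)`, which can
#' never return exactly zero.
#'
#' @param observed Observed group-mean score.
#' @param group_null Numeric vector of null group means (non-empty).
#' @return The one-sided p-value.
#' @export
permutation_p <- function(observed, group_null) {
  if (length(group_null) == 0) stop("`group_null` must be non-empty")
  (1 + sum(group_null >= observed)) / (1 + length(group_null))
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment with monotonicity enforcement, as used when
#' testing several regions of interest simultaneously.
#'
#' @param pvalues Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Paired within-subject contrast of two conditions
#'
#' Paired t-test on within-subject differences (e.g. balanced accuracy in a
#' high-gain versus a low-gain session). This is the simple per-subject
#' contrast the pipeline exposes; full factorial mixed-model analyses are
#' left to downstream statistics software operating on the tidy table.
#'
#' @param scores_a,scores_b Equal-length score vectors, matched by subject.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return A tibble with `statistic`, `df`, `p_one_sided` (the p-value of
#'   the requested alternative), `p_adjusted`, `method`, `flag`, and
#'   `mean_difference` (a - b).
#' @export
paired_contrast <- function(scores_a, scores_b, alternative = "two.sided") {
  n <- length(scores_a)
  if (n != length(scores_b)) stop("scores must be matched by subject")
  if (n < 2) stop("need at least 2 subjects")
  d <- scores_a - scores_b
  if (stats::sd(d) < 1e-12) {
    m <- mean(d)
    p <- if (m == 0) 1 else 0
    return(tibble::tibble(statistic = if (m == 0) 0 else sign(m) * Inf,
                          df = n - 1, p_one_sided = p, p_adjusted = NA_real_,
                          method = "paired t-test", flag = "zero variance",
                          mean_difference = m))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = alternative)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_one_sided = tt$p.value, p_adjusted = NA_real_,
                 method = "paired t-test", flag = NA_character_,
                 mean_difference = mean(d))
}
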