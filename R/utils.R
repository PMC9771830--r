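#' Signed circular difference in degrees
#'
#' Maps `a - b` onto the half-open interval (-180, 180], so that the
#' diametrically opposite direction is reported as +180 (never -180).
#'
#' @param a,b Angles in degrees (vectors recycle).
#' @return Signed difference in degrees, in (-180, 180].
#' @export
#' @examples
#' circ_diff(350, 10)   # -20
#' circ_diff(90, 270)   # 180, not -180
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Mixes the master seed with condition, subject and stage indices through a
#' linear-congruential step so that every randomized stage of a study has its
#' own reproducible stream. Results stay below 2^31.
#'
#' @param master Integer master seed.
#' @param subject,condition,stage Non-negative integer indices (stage may be
#'   a name from the internal stage table).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, subject = 0L, condition = 0L, stage = 0L) {
  if (is.character(stage)) {
    stages <- c(trajectory = 1, feedback = 2, bold = 3, decode = 4,
                permutation = 5, chance = 6)
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stage <- stages[[stage]]
  }
  x <- as.double(master) %% 2147483647
  for (k in c(condition, subject, stage)) {
    x <- (x * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

# stop() unless all arguments are single finite positive numbers
check_positive_scalar <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("`", nm[i], "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
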