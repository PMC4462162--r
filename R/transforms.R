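## Deterministic phenotype transforms shared by both analysis tracks.

#' Square-root transform of age at onset
#'
#' Age at onset of depression is positively skewed; the analysis models it on
#' the square-root scale, which brings it close to normality.
#'
#' @param aao Numeric vector of ages at onset in years (non-negative).
#' @return `sqrt(aao)`.
#' @export
#' @examples
#' sqrt_aao(25)  # 5
sqrt_aao <- function(aao) {
  if (any(aao < 0, na.rm = TRUE)) stop("age at onset must be non-negative")
  sqrt(aao)
}

#' Log episode frequency
#'
#' Episode frequency is the lifetime number of depressive episodes divided by
#' illness duration (age minus age at onset).  Short or zero durations are
#' floored so the rate and its logarithm stay finite.
#'
#' @param count Lifetime episode counts (>= 1 under recurrent-case
#'   ascertainment).
#' @param duration Illness duration in years.
#' @param floor Minimum duration in years used in the denominator
#'   (default 0.5).
#' @return `log(count / pmax(duration, floor))`.
#' @export
#' @examples
#' ln_episode_frequency(4, 20)  # log(0.2)
ln_episode_frequency <- function(count, duration, floor = 0.5) {
  if (any(count < 1, na.rm = TRUE)) stop("episode count must be >= 1 for a log frequency")
  if (any(duration < 0, na.rm = TRUE)) stop("duration must be non-negative")
  stopifnot(floor > 0)
  log(count / pmax(duration, floor))
}

#' Log-duration exposure offset
#'
#' Offset used by the count models: the log of illness duration, floored so
#' the log is finite for subjects whose onset is at (or very near) their
#' current age.
#'
#' @inheritParams ln_episode_frequency
#' @return `log(pmax(duration, floor))`.
#' @export
log_duration_offset <- function(duration, floor = 0.5) {
  if (any(duration < 0, na.rm = TRUE)) stop("duration must be non-negative")
  stopifnot(floor > 0)
  log(pmax(duration, floor))
}

#' Blom rank-based inverse-normal transform
#'
#' Maps values to normal scores `qnorm((r - 3/8) / (n + 1/4))` where `r` is
#' the (average-tie) rank and `n` the number of non-missing values.  Used to
#' normalise residuals before GREML.
#'
#' @param x Numeric vector, length >= 2 with at least two distinct values.
#' @return Numeric vector of Blom scores; `NA` stays `NA`.
#' @export
#' @examples
#' blom_rank_normalize(c(3, 1, 2))
blom_rank_normalize <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x[ok])) < 2L) stop("all values identical: ranks are degenerate")
  r <- rank(x[ok], ties.method = "average")
  z <- rep(NA_real_, length(x))
  z[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  z
}
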