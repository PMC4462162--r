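## Sibling variance decomposition and maximal-heritability bounds.

#' Full-sibling phenotypic covariance and correlation
#'
#' For full siblings the phenotypic covariance decomposes (ignoring epistasis)
#' as `COV_FS = 1/2 V_A + 1/4 V_D + V_C`: half the additive genetic variance,
#' a quarter of the dominance variance, plus the shared-environment variance.
#' The sibling intraclass correlation is `COV_FS / V_P`.
#'
#' @param V_A Additive genetic variance (>= 0).
#' @param V_D Dominance variance (>= 0).
#' @param V_C Shared-environment variance (>= 0).
#' @param V_P Total phenotypic variance (> 0, at least `V_A + V_D + V_C`).
#' @return List with `cov_fs` and `icc`.
#' @export
#' @examples
#' fullsib_covariance(V_A = 1, V_D = 0, V_C = 0, V_P = 2)  # icc = 0.25
fullsib_covariance <- function(V_A, V_D = 0, V_C = 0, V_P) {
  if (any(c(V_A, V_D, V_C, V_P) < 0)) stop("variance components must be non-negative")
  if (V_P == 0) stop("V_P must be positive")
  if (V_A + V_D + V_C > V_P + 1e-12) stop("V_A + V_D + V_C exceeds V_P")
  cov_fs <- 0.5 * V_A + 0.25 * V_D + V_C
  list(cov_fs = cov_fs, icc = cov_fs / V_P)
}

#' Maximal heritability from a sibling ICC
#'
#' Twice the full-sibling correlation equals narrow-sense heritability when
#' dominance and shared environment are negligible, and otherwise
#' overestimates it; `2 * ICC` (clipped at 1) is therefore an upper bound,
#' the "maximal heritability".  Confidence limits, if supplied, are
#' transformed the same way.
#'
#' @param icc Intraclass correlation in \[0, 1\] (an [IccEstimate][residual_icc]
#'   object is also accepted).
#' @param ci_low,ci_high Optional confidence limits for the ICC.
#' @return A list with `h2_max` and, when limits were given, `ci_low` and
#'   `ci_high`; for a bare numeric `icc` with no limits, the numeric bound
#'   itself.
#' @export
#' @examples
#' maximal_heritability(0.278)  # 0.556
maximal_heritability <- function(icc, ci_low = NULL, ci_high = NULL) {
  if (inherits(icc, "famvar_icc")) {
    ci_low <- icc$ci_low
    ci_high <- icc$ci_high
    icc <- icc$icc
  }
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) stop("icc must lie in [0, 1]")
  h2 <- pmin(2 * icc, 1)
  if (is.null(ci_low) && is.null(ci_high)) return(h2)
  list(h2_max = h2,
       ci_low = if (!is.null(ci_low)) pmin(pmax(2 * ci_low, 0), 1),
       ci_high = if (!is.null(ci_high)) pmin(2 * ci_high, 1))
}
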