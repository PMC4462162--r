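## Analytic power for GREML variance-component detection in unrelated samples.
##
## In samples of nominally unrelated individuals the sampling variance of the
## SNP-heritability estimate is approximately var(h2_hat) = 2 / (n^2 * var(A)),
## where var(A) is the variance of the off-diagonal GRM entries (about 2e-5
## for unrelated Europeans on common genotyping arrays).  The test of
## sigma2_g = 0 then has non-centrality NCP = h2^2 / var(h2_hat).

#' Power to detect a SNP heritability by GREML
#'
#' @param n Number of unrelated individuals.
#' @param h2 True SNP heritability (proportion of phenotypic variance).
#' @param var_aij Variance of the off-diagonal GRM entries (default `2e-5`,
#'   the conventional value for unrelated samples on common arrays; for a
#'   simulated panel of `M` independent SNPs use `1/M`).
#' @param alpha Test size (default 0.05).
#' @param sided `"two"` (default; chi-square test) or `"one"`
#'   (normal approximation).
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' greml_power(n = 3468, h2 = 0.25)
greml_power <- function(n, h2, var_aij = 2e-5, alpha = 0.05,
                        sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(n >= 2, var_aij > 0, alpha > 0, alpha < 1, h2 >= 0, h2 <= 1)
  var_h2 <- 2 / (n^2 * var_aij)
  ncp <- h2^2 / var_h2
  if (sided == "two") {
    crit <- stats::qchisq(1 - alpha, df = 1)
    stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  } else {
    stats::pnorm(sqrt(ncp) - stats::qnorm(1 - alpha))
  }
}

#' Smallest SNP heritability detectable at a target power
#'
#' Inverts [greml_power()]: finds the heritability whose non-centrality gives
#' the requested power at the requested test size.
#'
#' @inheritParams greml_power
#' @param target_power Desired power, in `(alpha, 1)` (default 0.8).
#' @return The detectable heritability (may exceed 1 for very small `n`, in
#'   which case the sample cannot reach the target power and an error is
#'   thrown).
#' @export
#' @examples
#' detectable_h2(n = 3468)  # about 0.255
detectable_h2 <- function(n, var_aij = 2e-5, target_power = 0.8, alpha = 0.05,
                          sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(n >= 2, var_aij > 0, target_power > alpha, target_power < 1)
  var_h2 <- 2 / (n^2 * var_aij)
  ncp <- if (sided == "two") {
    crit <- stats::qchisq(1 - alpha, df = 1)
    stats::uniroot(function(l) stats::pchisq(crit, 1, ncp = l, lower.tail = FALSE) - target_power,
                   interval = c(1e-8, 1e4), tol = 1e-12)$root
  } else {
    (stats::qnorm(target_power) + stats::qnorm(1 - alpha))^2
  }
  h2 <- sqrt(ncp * var_h2)
  if (h2 > 1) stop("target power unattainable at this sample size: detectable h2 > 1")
  h2
}
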