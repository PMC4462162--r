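## Intraclass correlation for overdispersed counts from the NB mixed model.
##
## Under the log-normal family intercept the marginal moments of a count with
## expectation mu are E(Y) = mu and Var(Y) = mu + alpha mu^2 e^{sigma2} +
## mu^2 (e^{sigma2} - 1); two members of one family share the latent
## intercept, so their covariance is mu^2 (e^{sigma2} - 1).  The
## variance-decomposition ICC is that covariance over the total variance.

# Shared constructor for ICC results.
new_icc_estimate <- function(icc, se, conf = 0.95, method = "empirical",
                             mu_marginal = NA_real_) {
  icc <- min(max(icc, 0), 1 - 1e-12)
  se <- max(0, se)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (icc > 0 && icc < 1 && se > 0) {
    se_l <- se / (icc * (1 - icc))
    lo <- inv_logit(logit(icc) - z * se_l)
    hi <- inv_logit(logit(icc) + z * se_l)
  } else {
    lo <- icc; hi <- icc
  }
  structure(list(icc = icc, se = se,
                 ci_low = lo, ci_high = hi,
                 ci_low_wald = max(0, icc - z * se),
                 ci_high_wald = min(1, icc + z * se),
                 conf = conf, method = method, mu_marginal = mu_marginal),
            class = "famvar_icc")
}

#' @export
print.famvar_icc <- function(x, ...) {
  cat(sprintf("ICC = %.4f (s.e. = %.4f, %g%% CI %.4f-%.4f) [%s]\n",
              x$icc, x$se, 100 * x$conf, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Closed-form count ICC for given model parameters
#'
#' @param mu Marginal count expectation (> 0).
#' @param sigma2 Family random-intercept variance on the log scale (>= 0).
#' @param alpha NB2 overdispersion (>= 0).
#' @param center_variance Optional additional log-scale variance shared by
#'   family members (e.g. a centre component); it is folded into both
#'   exponential factors.
#' @return The ICC `mu^2 (e^{s2} - 1) / (mu + alpha mu^2 e^{s2} +
#'   mu^2 (e^{s2} - 1))` with `s2 = sigma2 + center_variance`.
#' @export
#' @examples
#' carrasco_icc_value(mu = 2, sigma2 = 0.1, alpha = 0.5)  # 0.0908
carrasco_icc_value <- function(mu, sigma2, alpha, center_variance = 0) {
  stopifnot(mu > 0, sigma2 >= 0, alpha >= 0, center_variance >= 0)
  s2 <- sigma2 + center_variance
  vb <- mu^2 * (exp(s2) - 1)
  vt <- mu + alpha * mu^2 * exp(s2) + vb
  vb / vt
}

#' Variance-decomposition ICC for overdispersed counts
#'
#' Computes the count ICC from a fitted NB mixed model, with a delta-method
#' standard error propagating the joint covariance of `(beta0, log alpha,
#' log sigma2)` and a logit-scale confidence interval.  By default the
#' marginal expectation is evaluated per unit exposure (offset 0), `mu =
#' exp(beta0 + sigma2/2)`, so the ICC refers to the episode rate and is
#' exposure-free; `mu_mode = "empirical_mean"` plugs in the mean observed
#' rate instead.
#'
#' @param fit A `famvar_nbglmm` object (intercept must be the first column
#'   of its design).
#' @param mu_mode `"model_marginal"` (default) or `"empirical_mean"`.
#' @param center_variance Optional shared log-scale variance folded into the
#'   ICC (see [carrasco_icc_value()]).
#' @param conf Confidence level.
#' @return A `famvar_icc` object with `method = "nb_carrasco"`.
#' @export
carrasco_icc <- function(fit, mu_mode = c("model_marginal", "empirical_mean"),
                         center_variance = 0, conf = 0.95) {
  stopifnot(inherits(fit, "famvar_nbglmm"))
  mu_mode <- match.arg(mu_mode)
  if (fit$poisson) stop("need an NB fit (alpha estimated); Poisson fit given")
  s2 <- fit$sigma2_family
  a <- fit$alpha

  mu_of <- function(beta0, sigma2) {
    if (mu_mode == "model_marginal") exp(beta0 + (sigma2 + center_variance) / 2)
    else fit$mu_empirical
  }
  mu <- unname(mu_of(fit$beta[1L], s2))
  if (mu <= 0) stop("marginal expectation must be positive")
  icc <- carrasco_icc_value(mu, s2, a, center_variance)

  se <- 0
  if (!is.null(fit$varpar_cov) && s2 > 0) {
    pnames <- colnames(fit$varpar_cov)
    sel <- c(1L, match(c("log_alpha", "log_sigma2"), pnames))
    sel <- sel[!is.na(sel)]
    V <- fit$varpar_cov[sel, sel, drop = FALSE]
    th <- c(fit$beta[1L],
            if ("log_alpha" %in% pnames[sel]) log(max(a, 1e-12)),
            log(s2))
    f <- function(t) {
      b0 <- t[1L]
      aa <- if (length(t) == 3L) exp(t[2L]) else a
      ss <- exp(t[length(t)])
      carrasco_icc_value(mu_of(b0, ss), ss, aa, center_variance)
    }
    g <- num_grad(f, th)
    if (all(is.finite(g))) se <- sqrt(max(0, drop(t(g) %*% V %*% g)))
  }
  new_icc_estimate(icc, se, conf = conf, method = "nb_carrasco",
                   mu_marginal = mu)
}

#' Moment-based empirical ICC of episode frequency
#'
#' Model-free intraclass correlation of the observed episode rate
#' (`count / exposure`) across families, computed with the ordered-pair
#' (ANOVA-type) estimator; serves as the simulation oracle for the
#' closed-form count ICC.  The standard error is a leave-one-family-out
#' jackknife.
#'
#' @param counts Non-negative integer counts.
#' @param family_ids Family labels (>= 2 members in >= 30 families for a
#'   stable estimate).
#' @param offset_log Log-exposure per subject (default 0, i.e. counts are
#'   already rates).
#' @param conf Confidence level.
#' @return A `famvar_icc` object with `method = "empirical"`.
#' @export
empirical_icc_counts <- function(counts, family_ids, offset_log = 0,
                                 conf = 0.95) {
  x <- counts * exp(-rep_len(offset_log, length(counts)))
  fam <- factor(family_ids)
  keep <- !is.na(x)
  x <- x[keep]; fam <- droplevels(fam[keep])
  sizes <- table(fam)
  if (all(sizes < 2L)) stop("no families with at least 2 members")

  pair_icc <- function(x, fam) {
    # ordered within-family pairs against the pair-member mean/variance
    sf <- rowsum(x, fam); nf <- as.vector(table(fam))
    s2f <- rowsum(x^2, fam)
    npairs <- sum(nf * (nf - 1))
    if (npairs == 0) return(NA_real_)
    w <- (nf - 1)[as.integer(fam)]      # each subject appears in nf-1 ordered pairs (as first member)
    mbar <- sum(w * x) / npairs
    vbar <- sum(w * (x - mbar)^2) / npairs
    cross <- sum((sf - mbar * nf)^2 - (s2f - 2 * mbar * sf + mbar^2 * nf)) / npairs
    cross / vbar
  }
  icc <- pair_icc(x, fam)
  # delete-a-group jackknife over families (capped at 50 groups so the
  # cost stays linear in the sample size)
  lev <- levels(fam)
  if (length(lev) >= 5L) {
    G <- min(50L, length(lev))
    grp <- rep_len(seq_len(G), length(lev))[match(fam, lev)]
    jk <- vapply(seq_len(G), function(g) {
      keep <- grp != g
      pair_icc(x[keep], droplevels(fam[keep]))
    }, numeric(1))
    jk <- jk[is.finite(jk)]
    G <- length(jk)
    se <- sqrt((G - 1) / G * sum((jk - mean(jk))^2))
  } else se <- NA_real_
  new_icc_estimate(icc, ifelse(is.na(se), 0, se), conf = conf,
                   method = "empirical", mu_marginal = mean(x))
}
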