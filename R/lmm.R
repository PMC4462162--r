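## Three-level linear mixed models: subjects within families within centres.
##
## The REML optimum is found with lme4; the package evaluates its own
## closed-form REML log-likelihood for the nested random-intercept structure
## (Woodbury identity over a sparse random-effects design) both as an
## internal cross-check and to obtain, by numerical differentiation, the
## covariance matrix of the variance-parameter estimates that the
## delta-method ICC intervals need.

#' Fit a nested random-intercept linear mixed model by REML
#'
#' Fits `y = X beta + u_center + u_family + e` with independent Gaussian
#' random intercepts for centre (optional) and family, subjects nested within
#' families and families within centres.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full column rank; include an
#'   intercept column if one is wanted).
#' @param family_ids Family labels, one per observation.
#' @param center_ids Optional centre labels; when supplied every family must
#'   lie within a single centre.
#' @param varpar_cov Compute the covariance of the variance-parameter
#'   estimates by numeric differentiation of the REML log-likelihood
#'   (default TRUE; skip in tight simulation loops).
#' @return A `famvar_lmm` object: `beta`, `beta_cov`, `sigma2_center`,
#'   `sigma2_family`, `sigma2_e`, `loglik_reml`, `varpar_cov` (natural
#'   scale, rows/cols `sigma2_center`, `sigma2_family`, `sigma2_e`),
#'   `n_obs`, `n_families`, `converged`, and the underlying lme4 fit.
#' @export
fit_lmm_nested <- function(y, X, family_ids, center_ids = NULL,
                           varpar_cov = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(family_ids) != n)
    stop("y, X and family_ids must have matching lengths")
  if (!is.null(center_ids)) {
    if (length(center_ids) != n) stop("center_ids length mismatch")
    per_fam <- tapply(center_ids, family_ids, function(x) length(unique(x)))
    if (any(per_fam > 1L)) stop("families must be nested within a single centre")
  }
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")

  df <- as.data.frame(X)
  xn <- sprintf(".x%d", seq_len(ncol(X)))
  names(df) <- xn
  df$.y <- y
  df$.fam <- factor(family_ids)
  re <- "(1 | .fam)"
  if (!is.null(center_ids)) {
    df$.cen <- factor(center_ids)
    re <- "(1 | .cen) + (1 | .fam)"
  }
  form <- stats::as.formula(paste(".y ~ 0 +", paste(xn, collapse = " + "),
                                  "+", re))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = df, REML = TRUE, control = ctrl)

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2f <- vc$vcov[vc$grp == ".fam"]
  s2c <- if (!is.null(center_ids)) vc$vcov[vc$grp == ".cen"] else 0
  s2e <- vc$vcov[vc$grp == "Residual"]
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X) %||% xn
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L

  out <- structure(list(
    beta = beta,
    beta_cov = as.matrix(stats::vcov(fit)),
    sigma2_center = s2c, sigma2_family = s2f, sigma2_e = s2e,
    loglik_reml = as.numeric(stats::logLik(fit)),
    varpar_cov = NULL,
    n_obs = n, n_families = length(unique(family_ids)),
    has_center = !is.null(center_ids),
    converged = conv,
    y = y, X = X, family_ids = as.character(family_ids),
    center_ids = if (is.null(center_ids)) NULL else as.character(center_ids),
    lme4_fit = fit), class = "famvar_lmm")
  if (!conv)
    warning("lme4 reported convergence issues: ",
            paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  if (varpar_cov) out$varpar_cov <- lmm_varpar_cov(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.famvar_lmm <- function(x, ...) {
  cat("Nested REML linear mixed model\n")
  cat(sprintf("  n = %d observations, %d families%s\n", x$n_obs, x$n_families,
              if (x$has_center) ", centres included" else ""))
  cat(sprintf("  sigma2_center = %.4f, sigma2_family = %.4f, sigma2_e = %.4f\n",
              x$sigma2_center, x$sigma2_family, x$sigma2_e))
  cat(sprintf("  REML log-likelihood = %.3f\n", x$loglik_reml))
  invisible(x)
}

#' REML log-likelihood of the nested random-intercept model
#'
#' Direct evaluation of the restricted log-likelihood for given variance
#' components, using the Woodbury identity over the sparse random-effects
#' design; fixed effects are profiled out in the REML sense.  Used to
#' cross-check the lme4 optimum and to differentiate numerically for
#' variance-parameter covariances.
#'
#' @inheritParams fit_lmm_nested
#' @param sigma2_center,sigma2_family,sigma2_e Variance components (centre
#'   variance ignored when `center_ids` is NULL).
#' @return The restricted log-likelihood (including its constant).
#' @export
reml_loglik_nested <- function(y, X, family_ids, center_ids = NULL,
                               sigma2_center = 0, sigma2_family, sigma2_e) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(sigma2_e > 0, sigma2_family >= 0, sigma2_center >= 0)

  Zs <- list()
  gs <- numeric(0)
  if (sigma2_family > 0) {
    f <- factor(family_ids)
    Zs <- c(Zs, list(Matrix::sparse.model.matrix(~ 0 + f)))
    gs <- c(gs, rep(sigma2_family, nlevels(f)))
  }
  if (!is.null(center_ids) && sigma2_center > 0) {
    cen <- factor(center_ids)
    Zs <- c(Zs, list(Matrix::sparse.model.matrix(~ 0 + cen)))
    gs <- c(gs, rep(sigma2_center, nlevels(cen)))
  }

  if (!length(Zs)) {
    # pure fixed-effects model: V = sigma2_e I
    qrX <- qr(X)
    res <- qr.resid(qrX, y)
    quad <- sum(res^2) / sigma2_e
    ldV <- n * log(sigma2_e)
    ldXVX <- determinant(crossprod(X) / sigma2_e, logarithm = TRUE)$modulus
  } else {
    Z <- do.call(cbind, Zs)
    q <- ncol(Z)
    M <- Matrix::crossprod(Z) / sigma2_e + Matrix::Diagonal(q, 1 / gs)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
    ldM <- as.numeric(Matrix::determinant(M, logarithm = TRUE)$modulus)
    ldV <- n * log(sigma2_e) + ldM + sum(log(gs))
    Vinv <- function(r) {
      Ztr <- Matrix::crossprod(Z, r)
      as.matrix(r / sigma2_e -
                  (Z %*% Matrix::solve(ch, Ztr)) / sigma2_e^2)
    }
    Viy <- Vinv(y)
    ViX <- Vinv(X)
    XtViX <- crossprod(X, ViX)
    XtViy <- crossprod(X, Viy)
    bhat <- solve(XtViX, XtViy)
    quad <- sum(y * Viy) - sum(XtViy * bhat)
    ldXVX <- determinant(XtViX, logarithm = TRUE)$modulus
  }
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + ldV + ldXVX + quad))
}

# Covariance of (sigma2_center, sigma2_family, sigma2_e) estimates from the
# numeric Hessian of the REML log-likelihood on the log-variance scale.
# Components estimated at (or numerically on) the zero boundary get zero
# rows/columns: no curvature information is available there.
lmm_varpar_cov <- function(fit) {
  v <- c(sigma2_center = fit$sigma2_center,
         sigma2_family = fit$sigma2_family,
         sigma2_e = fit$sigma2_e)
  tol <- 1e-8 * stats::var(fit$y)
  active <- v > tol
  if (!fit$has_center) active["sigma2_center"] <- FALSE
  V <- matrix(0, 3, 3, dimnames = list(names(v), names(v)))
  if (!any(active)) return(V)
  idx <- which(active)
  f <- function(logv) {
    vv <- v
    vv[idx] <- exp(logv)
    reml_loglik_nested(fit$y, fit$X, fit$family_ids, fit$center_ids,
                       sigma2_center = vv["sigma2_center"],
                       sigma2_family = vv["sigma2_family"],
                       sigma2_e = vv["sigma2_e"])
  }
  H <- num_hessian(f, log(v[idx]), h = 1e-4)
  cov_log <- safe_cov_from_hessian(-H)
  D <- diag(v[idx], nrow = length(idx))
  V[idx, idx] <- D %*% cov_log %*% D
  V
}

#' Likelihood-ratio test for the family variance component
#'
#' Boundary-corrected REML likelihood-ratio test of `sigma2_family = 0`.
#' The reduced fit must be the full fit with the family random intercept
#' removed, on the same data with the same fixed effects.  The null
#' distribution is the 50:50 mixture of a point mass at zero and chi-square
#' with 1 df, so `p = 0.5 * P(chisq_1 > statistic)` (0.5 at a zero
#' statistic).
#'
#' @param fit_full,fit_reduced `famvar_lmm` fits with and without the family
#'   random intercept.
#' @return List with `statistic` and `p_value`.
#' @export
lrt_family_variance <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "famvar_lmm"), inherits(fit_reduced, "famvar_lmm"))
  if (fit_full$n_obs != fit_reduced$n_obs ||
      !isTRUE(all.equal(fit_full$y, fit_reduced$y)) ||
      !isTRUE(all.equal(unname(fit_full$X), unname(fit_reduced$X))))
    stop("full and reduced models must be fitted to the same data")
  stat <- max(0, 2 * (fit_full$loglik_reml - fit_reduced$loglik_reml))
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

# Reduced-model convenience: refit without the family random intercept.
# With no centre level this is the plain fixed-effects regression, whose
# REML log-likelihood comes from reml_loglik_nested at the residual MLE.
drop_family_refit <- function(fit) {
  if (fit$has_center) {
    df <- as.data.frame(fit$X)
    xn <- sprintf(".x%d", seq_len(ncol(fit$X)))
    names(df) <- xn
    df$.y <- fit$y
    df$.cen <- factor(fit$center_ids)
    form <- stats::as.formula(paste(".y ~ 0 +", paste(xn, collapse = " + "),
                                    "+ (1 | .cen)"))
    ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore",
                              check.conv.singular = "ignore")
    f0 <- lme4::lmer(form, data = df, REML = TRUE, control = ctrl)
    ll <- as.numeric(stats::logLik(f0))
  } else {
    n <- fit$n_obs; p <- ncol(fit$X)
    rss <- sum(qr.resid(qr(fit$X), fit$y)^2)
    s2 <- rss / (n - p)
    ll <- reml_loglik_nested(fit$y, fit$X, fit$family_ids, NULL,
                             sigma2_family = 0, sigma2_e = s2)
  }
  out <- fit
  out$sigma2_family <- 0
  out$loglik_reml <- ll
  out$varpar_cov <- NULL
  out
}

#' Family-level residual intraclass correlation from an LMM fit
#'
#' The residual ICC is the share of the residual variance of the response
#' (after the fixed effects) attributable to family membership.  By default
#' it conditions on centre, `icc = sigma2_family / (sigma2_family +
#' sigma2_e)` -- the expected correlation of two siblings from the same
#' centre; with `include_center = TRUE` the centre variance enters numerator
#' and denominator.  The standard error comes from the delta method on the
#' variance-parameter covariance; the confidence interval is computed on the
#' logit scale and back-transformed (a symmetric Wald interval is also
#' reported).
#'
#' @param fit A `famvar_lmm` object with `varpar_cov`.
#' @param include_center Fold the centre variance into the ICC (default
#'   FALSE).
#' @param conf Confidence level (default 0.95).
#' @return An [IccEstimate][print.famvar_icc] (`famvar_icc`): `icc`, `se`,
#'   `ci_low`, `ci_high`, `ci_low_wald`, `ci_high_wald`, `method`.
#' @export
residual_icc <- function(fit, include_center = FALSE, conf = 0.95) {
  stopifnot(inherits(fit, "famvar_lmm"))
  s2c <- if (include_center) fit$sigma2_center else 0
  num <- s2c + fit$sigma2_family
  den <- num + fit$sigma2_e
  if (den <= 0) stop("total variance is zero")
  icc <- num / den
  # delta method on the natural-scale variance components
  grad <- c(sigma2_center = if (include_center) fit$sigma2_e / den^2 else 0,
            sigma2_family = fit$sigma2_e / den^2,
            sigma2_e = -num / den^2)
  V <- fit$varpar_cov
  if (is.null(V)) V <- lmm_varpar_cov(fit)
  se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  new_icc_estimate(icc, se, conf = conf, method = "lmm_residual")
}

#' Residuals from a nested LMM
#'
#' Marginal residuals `y - X beta_hat`, optionally minus predicted (BLUP)
#' random effects.  For the GREML workflow on unrelated individuals the
#' convention is to subtract the fixed effects and the centre BLUPs but no
#' family level (none is estimable there); `level = "center"` does that when
#' a centre level exists and otherwise equals `"none"`.
#'
#' @param fit A `famvar_lmm` object.
#' @param level Which random effects to subtract: `"center"` (default),
#'   `"none"` (marginal residuals), or `"all"` (conditional residuals).
#' @return Residual vector.
#' @export
lmm_residuals <- function(fit, level = c("center", "none", "all")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "famvar_lmm"))
  r <- fit$y - drop(fit$X %*% fit$beta)
  if (level == "none") return(r)
  re <- lme4::ranef(fit$lme4_fit)
  if (level %in% c("center", "all") && fit$has_center && !is.null(re$.cen)) {
    u <- re$.cen[["(Intercept)"]]
    names(u) <- rownames(re$.cen)
    r <- r - u[fit$center_ids]
  }
  if (level == "all" && !is.null(re$.fam)) {
    u <- re$.fam[["(Intercept)"]]
    names(u) <- rownames(re$.fam)
    r <- r - u[fit$family_ids]
  }
  unname(r)
}
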