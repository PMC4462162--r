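## Negative-binomial mixed model for episode counts, fitted by maximising the
## exact marginal likelihood with adaptive Gauss-Hermite quadrature (AGHQ).
##
## Model: y_ij | b_j ~ NB2(m_ij, alpha), log m_ij = x_ij' beta + offset_ij +
## b_j, b_j ~ N(0, sigma2), with conditional variance m + alpha m^2.  Each
## family contributes the integral of its conditional likelihood over b_j;
## the quadrature grid is recentred at the per-family posterior mode and
## scaled by the posterior curvature ("adaptive"), so few nodes (7 by
## default) suffice.

#' Gauss-Hermite nodes and weights
#'
#' Nodes/weights for integrals against `exp(-z^2)`, computed by the
#' Golub-Welsch eigenvalue method (deterministic, no tables).
#'
#' @param n Number of nodes (>= 1).
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Conditional NB2 log-density; alpha ~ 0 falls back to Poisson.
cond_count_loglik <- function(y, mu, alpha) {
  if (alpha > 1e-10) stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)
  else stats::dpois(y, mu, log = TRUE)
}

# Posterior modes of the family random intercepts, Newton iterations
# vectorised across families (the score (y-m)/(1+alpha*m) and curvature
# m(1+alpha*y)/(1+alpha*m)^2 are exact for alpha >= 0).
family_modes <- function(y, eta0, alpha, sigma2, fi, nf, b0 = NULL,
                         tol = 1e-10, maxit = 50L) {
  b <- if (is.null(b0)) numeric(nf) else b0
  obj <- function(b) {
    m <- exp(eta0 + b[fi])
    drop(rowsum(cond_count_loglik(y, m, alpha), fi)) - b^2 / (2 * sigma2)
  }
  o <- obj(b)
  for (it in seq_len(maxit)) {
    m <- exp(eta0 + b[fi])
    S <- drop(rowsum((y - m) / (1 + alpha * m), fi)) - b / sigma2
    Hn <- drop(rowsum(m * (1 + alpha * y) / (1 + alpha * m)^2, fi)) + 1 / sigma2
    step <- S / Hn
    repeat {
      bn <- b + step
      on <- obj(bn)
      if (all(on >= o - 1e-12) || max(abs(step)) < 1e-14) break
      bad <- on < o - 1e-12
      step[bad] <- step[bad] / 2
    }
    moved <- max(abs(bn - b))
    b <- bn; o <- on
    if (moved < tol) break
  }
  m <- exp(eta0 + b[fi])
  curv <- drop(rowsum(m * (1 + alpha * y) / (1 + alpha * m)^2, fi)) + 1 / sigma2
  list(b = b, curv = curv)
}

#' Marginal log-likelihood of the count mixed model by AGHQ
#'
#' Evaluates the exact marginal log-likelihood at given parameter values with
#' an `n_quad`-point adaptive Gauss-Hermite rule; useful for checking
#' quadrature convergence (compare low against high node counts).
#'
#' @param beta Fixed-effect coefficients (conformable with `X`).
#' @param alpha NB2 overdispersion (>= 0; 0 gives the Poisson mixed model).
#' @param sigma2 Family random-intercept variance (> 0).
#' @param y Non-negative integer counts.
#' @param X Fixed-effect design matrix.
#' @param offset_log Log-exposure offset vector.
#' @param family_ids Family labels.
#' @param n_quad Number of quadrature nodes (default 7).
#' @param modes Optional warm-start posterior modes (internal use).
#' @return Scalar marginal log-likelihood (attribute `modes` carries the
#'   per-family posterior modes).
#' @export
nb_glmm_loglik <- function(beta, alpha, sigma2, y, X, offset_log, family_ids,
                           n_quad = 7, modes = NULL) {
  X <- as.matrix(X)
  fam <- factor(family_ids)
  fi <- as.integer(fam)
  nf <- nlevels(fam)
  eta0 <- drop(X %*% beta) + offset_log
  md <- family_modes(y, eta0, alpha, sigma2, fi, nf, b0 = modes)
  tau <- 1 / sqrt(md$curv)
  gh <- gauss_hermite(n_quad)
  H <- matrix(NA_real_, nf, n_quad)
  for (k in seq_len(n_quad)) {
    bk <- md$b + sqrt(2) * tau * gh$nodes[k]
    ll_i <- cond_count_loglik(y, exp(eta0 + bk[fi]), alpha)
    H[, k] <- drop(rowsum(ll_i, fi)) +
      stats::dnorm(bk, 0, sqrt(sigma2), log = TRUE) +
      log(gh$weights[k]) + gh$nodes[k]^2
  }
  ll <- sum(log(sqrt(2) * tau) + row_logsumexp(H))
  attr(ll, "modes") <- md$b
  ll
}

#' Fit the negative-binomial mixed model for episode counts
#'
#' Maximises the AGHQ marginal likelihood over the fixed effects, the log
#' overdispersion and the log family variance.  Centre enters as fixed-effect
#' dummies in `X` when wanted (two-level model: subjects within families).
#'
#' @inheritParams nb_glmm_loglik
#' @param n_quad Number of adaptive quadrature nodes (default 7; >= 3).
#' @param poisson Fix `alpha = 0` and fit the Poisson mixed model.
#' @param no_random Drop the family random intercept (`sigma2 = 0`), giving
#'   a plain fixed-effects count regression; used as the reduced model in
#'   the boundary test of the family variance.
#' @param varpar_cov Compute the joint covariance of `(beta, log alpha,
#'   log sigma2)` from the numeric Hessian of the marginal log-likelihood
#'   (default TRUE).
#' @return A `famvar_nbglmm` object: `beta`, `alpha`, `sigma2_family`,
#'   `loglik`, `varpar_cov`, `n_quad`, `modes` (per-family posterior modes),
#'   `boundary` flags, `converged`, plus the data needed for residuals.
#' @export
fit_nb_glmm <- function(y, X, offset_log = 0, family_ids, n_quad = 7,
                        poisson = FALSE, no_random = FALSE,
                        varpar_cov = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (nrow(X) != n || length(family_ids) != n)
    stop("y, X and family_ids must have matching lengths")
  if (n_quad < 3) stop("need at least 3 quadrature nodes")
  offset_log <- rep_len(offset_log, n)
  if (any(!is.finite(offset_log))) stop("offset must be finite")
  if (stats::var(y) == 0)
    stop("all counts identical: overdispersion is not identifiable")

  p <- ncol(X)
  # optimise with columns scaled to [-1, 1] so gradient components are
  # comparable (an age column on the year scale otherwise dominates)
  col_scale <- apply(abs(X), 2L, max)
  col_scale[col_scale == 0] <- 1
  X_opt <- sweep(X, 2L, col_scale, "/")
  start_fit <- stats::glm.fit(X_opt, y, offset = offset_log,
                              family = stats::poisson())
  beta0 <- start_fit$coefficients
  mu0 <- start_fit$fitted.values
  alpha0 <- max(0.05, sum((y - mu0)^2 - mu0) / sum(mu0^2))
  lb <- -15; ub <- 8
  env <- new.env()
  env$modes <- NULL

  make_obj <- function(with_alpha) function(par) {
    beta <- par[seq_len(p)]
    alpha <- if (with_alpha) exp(par[p + 1L]) else 0
    if (no_random) {
      mu <- exp(drop(X_opt %*% beta) + offset_log)
      return(-sum(cond_count_loglik(y, mu, alpha)))
    }
    sigma2 <- exp(par[length(par)])
    ll <- nb_glmm_loglik(beta, alpha, sigma2, y, X_opt, offset_log,
                         family_ids, n_quad = n_quad, modes = env$modes)
    env$modes <- attr(ll, "modes")
    -as.numeric(ll)
  }

  nv <- if (no_random) 0L else 1L  # log sigma2 present?
  if (poisson) {
    par0 <- c(beta0, if (nv) log(0.2))
    obj <- make_obj(FALSE)
    lower <- c(rep(-Inf, p), rep(lb, nv)); upper <- c(rep(Inf, p), rep(ub, nv))
  } else {
    par0 <- c(beta0, log(alpha0), if (nv) log(0.2))
    obj <- make_obj(TRUE)
    lower <- c(rep(-Inf, p), lb, rep(lb, nv))
    upper <- c(rep(Inf, p), ub, rep(ub, nv))
  }
  if (poisson && no_random) {
    # closed-form branch: Poisson regression has no free dispersion
    beta <- stats::glm.fit(X, y, offset = offset_log,
                           family = stats::poisson())$coefficients
    names(beta) <- colnames(X) %||% sprintf("x%d", seq_len(p))
    mu <- exp(drop(X %*% beta) + offset_log)
    out <- structure(list(
      beta = beta, alpha = 0, sigma2_family = 0,
      loglik = sum(stats::dpois(y, mu, log = TRUE)), n_quad = n_quad,
      boundary = c(alpha = FALSE, sigma2 = FALSE), converged = TRUE,
      poisson = TRUE, no_random = TRUE, varpar_cov = NULL,
      modes = numeric(length(unique(family_ids))),
      y = y, X = X, offset_log = offset_log,
      family_ids = as.character(family_ids),
      mu_empirical = mean(y * exp(-offset_log))), class = "famvar_nbglmm")
    return(out)
  }
  opt <- stats::nlminb(par0, obj, lower = lower, upper = upper,
                       control = list(eval.max = 10000, iter.max = 2000,
                                      rel.tol = 1e-9))
  par <- opt$par
  beta <- par[seq_len(p)] / col_scale  # back to the original column scale
  names(beta) <- colnames(X) %||% sprintf("x%d", seq_len(p))
  alpha <- if (poisson) 0 else unname(exp(par[p + 1L]))
  sigma2 <- if (no_random) 0 else unname(exp(par[length(par)]))
  boundary <- c(alpha = !poisson && par[p + 1L] <= lb + 1e-6,
                sigma2 = !no_random && par[length(par)] <= lb + 1e-6)
  # "singular convergence" is nlminb's report of an optimum with a singular
  # Hessian, which is expected when alpha or sigma2 sits on its boundary
  converged <- opt$convergence == 0 ||
    grepl("singular convergence|X-convergence|absolute function",
          opt$message %||% "")
  if (!converged) {
    # nlminb can under-report on flat surfaces; accept when the gradient of
    # the marginal log-likelihood vanishes at the returned point (bounded
    # parameters may carry outward gradients)
    g <- num_grad(function(p) -obj(p), opt$par)
    free <- opt$par > lower + 1e-6 & opt$par < upper - 1e-6
    converged <- all(abs(g[free]) < 1e-2)
    if (!converged)
      warning("nlminb did not report convergence: ", opt$message,
              " (max free-gradient ", signif(max(abs(g[free])), 3), ")")
  }

  if (no_random) {
    ll <- -obj(par)
    modes <- numeric(length(unique(family_ids)))
  } else {
    ll <- nb_glmm_loglik(beta, alpha, sigma2, y, X, offset_log, family_ids,
                         n_quad = n_quad, modes = env$modes)
    modes <- attr(ll, "modes")
  }
  out <- structure(list(
    beta = beta, alpha = alpha, sigma2_family = sigma2,
    loglik = as.numeric(ll), n_quad = n_quad,
    boundary = boundary, converged = converged, poisson = poisson,
    no_random = no_random,
    varpar_cov = NULL, modes = modes,
    y = y, X = X, offset_log = offset_log,
    family_ids = as.character(family_ids),
    mu_empirical = mean(y * exp(-offset_log))), class = "famvar_nbglmm")
  if (varpar_cov && !no_random) out$varpar_cov <- nbglmm_varpar_cov(out)
  out
}

#' @export
print.famvar_nbglmm <- function(x, ...) {
  cat(if (x$poisson) "Poisson" else "Negative-binomial",
      "mixed model (adaptive Gauss-Hermite,", x$n_quad, "nodes)\n")
  cat(sprintf("  n = %d observations, %d families\n", length(x$y),
              length(unique(x$family_ids))))
  if (!x$poisson) cat(sprintf("  alpha = %.4f\n", x$alpha))
  cat(sprintf("  sigma2_family = %.4f, log-likelihood = %.3f\n",
              x$sigma2_family, x$loglik))
  invisible(x)
}

# Joint covariance of (beta, log alpha, log sigma2) by numerically
# differentiating the marginal log-likelihood; boundary parameters get zero
# rows/columns.
nbglmm_varpar_cov <- function(fit) {
  p <- length(fit$beta)
  nm <- c(names(fit$beta),
          if (!fit$poisson) "log_alpha", "log_sigma2")
  par <- c(fit$beta, if (!fit$poisson) log(max(fit$alpha, 1e-12)),
           log(max(fit$sigma2_family, 1e-12)))
  active <- rep(TRUE, length(par))
  if (!fit$poisson && fit$boundary["alpha"]) active[p + 1L] <- FALSE
  if (fit$boundary["sigma2"]) active[length(par)] <- FALSE
  V <- matrix(0, length(par), length(par), dimnames = list(nm, nm))
  idx <- which(active)
  f <- function(th) {
    pp <- par
    pp[idx] <- th
    beta <- pp[seq_len(p)]
    alpha <- if (fit$poisson) 0 else exp(pp[p + 1L])
    sigma2 <- exp(pp[length(pp)])
    as.numeric(nb_glmm_loglik(beta, alpha, sigma2, fit$y, fit$X,
                              fit$offset_log, fit$family_ids,
                              n_quad = fit$n_quad, modes = fit$modes))
  }
  H <- num_hessian(f, par[idx], h = 1e-4)
  V[idx, idx] <- safe_cov_from_hessian(-H)
  V
}

#' Poisson versus negative-binomial comparison
#'
#' Fits both mixed models on the same data and tests `alpha > 0` with the
#' boundary-corrected likelihood-ratio test (50:50 mixture of a point mass
#' and chi-square 1).
#'
#' @inheritParams fit_nb_glmm
#' @return List with `fit_poisson`, `fit_nb`, and `lrt_overdispersion`
#'   (`statistic`, `p_value`).
#' @export
poisson_vs_nb_comparison <- function(y, X, offset_log = 0, family_ids,
                                     n_quad = 7, varpar_cov = FALSE) {
  fp <- fit_nb_glmm(y, X, offset_log, family_ids, n_quad = n_quad,
                    poisson = TRUE, varpar_cov = varpar_cov)
  fn <- fit_nb_glmm(y, X, offset_log, family_ids, n_quad = n_quad,
                    poisson = FALSE, varpar_cov = varpar_cov)
  stat <- max(0, 2 * (fn$loglik - fp$loglik))
  list(fit_poisson = fp, fit_nb = fn,
       lrt_overdispersion = list(
         statistic = stat,
         p_value = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Negative-binomial deviance residuals
#'
#' Per-subject NB2 deviance residuals
#' `d = sign(y - m) * sqrt(2 * (y log(y/m) - (y + 1/alpha) *
#' log((1 + alpha y) / (1 + alpha m))))`, with `y log(y/m) := 0` at `y = 0`
#' and the Poisson deviance as the `alpha -> 0` limit.  By default the
#' fitted mean is population-averaged (fixed effects plus offset, no family
#' effect) -- the convention for downstream GREML on unrelated individuals;
#' `conditional = TRUE` adds the posterior-mode family effects.
#'
#' @param fit A `famvar_nbglmm` object.
#' @param conditional Use mode-conditioned means (default FALSE).
#' @return Residual vector.
#' @export
nb_deviance_residuals <- function(fit, conditional = FALSE) {
  stopifnot(inherits(fit, "famvar_nbglmm"))
  eta <- drop(fit$X %*% fit$beta) + fit$offset_log
  if (conditional) {
    fi <- as.integer(factor(fit$family_ids))
    eta <- eta + fit$modes[fi]
  }
  m <- exp(eta)
  y <- fit$y
  a <- fit$alpha
  t1 <- ifelse(y > 0, y * log(y / m), 0)
  if (a > 1e-8) {
    t2 <- (y + 1 / a) * log((1 + a * y) / (1 + a * m))
  } else {
    t2 <- y - m  # Poisson limit of the second bracket
  }
  sign(y - m) * sqrt(pmax(0, 2 * (t1 - t2)))
}
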