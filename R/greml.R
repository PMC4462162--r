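## GREML: REML estimation of the genetic variance captured by a GRM.
##
## Model: y = X b + g + e with g ~ N(0, A sigma2_g), e ~ N(0, I sigma2_e).
## A single eigendecomposition of the GRM rotates the problem to a diagonal
## covariance, after which every AI-REML iteration (and any likelihood
## evaluation, e.g. for grid-search cross-checks) costs O(N p^2).

# Rotate the problem once: returns eigenvalues and rotated response/design.
greml_rotate <- function(y, X, grm) {
  n <- length(y)
  stopifnot(inherits(grm, "famvar_grm"), nrow(grm$values) == n,
            nrow(X) == n)
  e <- eigen(grm$values, symmetric = TRUE)
  if (min(e$values) < -0.01 * max(abs(e$values)))
    stop("GRM is not positive semidefinite beyond tolerance")
  list(lambda = pmax(e$values, 0), ystar = drop(crossprod(e$vectors, y)),
       Xstar = crossprod(e$vectors, X))
}

# Restricted log-likelihood at (vg, ve) in the rotated space.
greml_loglik_rot <- function(vg, ve, rot) {
  d <- vg * rot$lambda + ve
  if (any(d <= 0)) return(-Inf)
  n <- length(rot$ystar); p <- ncol(rot$Xstar)
  Xd <- rot$Xstar / d
  XtViX <- crossprod(rot$Xstar, Xd)
  XtViy <- crossprod(Xd, rot$ystar)
  bhat <- solve(XtViX, XtViy)
  quad <- sum(rot$ystar^2 / d) - sum(XtViy * bhat)
  ld <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + sum(log(d)) + ld + quad))
}

#' Exact GREML restricted log-likelihood, as a function factory
#'
#' Returns a function `(sigma2_g, sigma2_e) -> REML log-likelihood` for the
#' given data, sharing one eigendecomposition across calls.  Used for
#' grid-search cross-checks of the AI-REML optimum.
#'
#' @param y Phenotype vector.
#' @param covariates Optional covariate matrix (an intercept is always
#'   added).
#' @param grm A `famvar_grm` over the same individuals, in the same order.
#' @return Function of `(sigma2_g, sigma2_e)`.
#' @export
greml_loglik_fun <- function(y, covariates = NULL, grm) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  rot <- greml_rotate(y, X, grm)
  function(sigma2_g, sigma2_e) greml_loglik_rot(sigma2_g, sigma2_e, rot)
}

#' Fit GREML variance components by AI-REML
#'
#' Average-information REML for `y = X b + g + e`, `g ~ N(0, A sigma2_g)`,
#' with an EM-REML fallback whenever an AI step fails or decreases the
#' likelihood.  Components are constrained non-negative (clipped at
#' `1e-8 * var(y)` during iteration).  The heritability standard error comes
#' from the delta method on the inverse average-information matrix, and the
#' test of `sigma2_g = 0` uses the boundary-corrected 50:50 chi-square
#' mixture.
#'
#' @inheritParams greml_loglik_fun
#' @param max_iter Maximum AI-REML iterations (default 100).
#' @param tol Convergence: absolute log-likelihood change below `tol`
#'   (default 1e-6) with score norm below 1e-4.
#' @return A `famvar_greml` object: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `loglik`, `loglik_null`, `lrt`, `p`, `n_used`, `converged`,
#'   `iterations`, `trajectory`.
#' @export
fit_greml <- function(y, covariates = NULL, grm, max_iter = 100, tol = 1e-6) {
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  rot <- greml_rotate(y, X, grm)
  n <- length(y); p <- ncol(X)
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy

  vg <- ve <- vy / 2
  ll <- greml_loglik_rot(vg, ve, rot)
  traj <- data.frame(iter = 0L, sigma2_g = vg, sigma2_e = ve, loglik = ll)
  converged <- FALSE
  score <- c(NA_real_, NA_real_)
  AI <- matrix(NA_real_, 2, 2)

  derivs <- function(vg, ve) {
    d <- vg * rot$lambda + ve
    Xd <- rot$Xstar / d
    XtViX <- crossprod(rot$Xstar, Xd)
    XtViX_inv <- solve(XtViX)
    bhat <- XtViX_inv %*% crossprod(Xd, rot$ystar)
    Py <- (rot$ystar - drop(rot$Xstar %*% bhat)) / d
    # tr(P A_i) for A_g = diag(lambda), A_e = I (rotated space)
    trP <- function(a) sum(a / d) - sum(XtViX_inv * crossprod(Xd * a, Xd))
    PAgPy <- {
      w <- rot$lambda * Py
      (w - drop(rot$Xstar %*% (XtViX_inv %*% crossprod(rot$Xstar, w / d)))) / d
    }
    PAePy <- {
      (Py - drop(rot$Xstar %*% (XtViX_inv %*% crossprod(rot$Xstar, Py / d)))) / d
    }
    # y'P A P y in symmetric form: (Py)' A (Py)
    yPAgPy <- sum(Py * rot$lambda * Py)
    yPAePy <- sum(Py * Py)
    sc <- 0.5 * c(yPAgPy - trP(rot$lambda), yPAePy - trP(rep(1, n)))
    AI <- 0.5 * matrix(c(
      sum((rot$lambda * Py) * PAgPy),
      sum((rot$lambda * Py) * PAePy),
      sum((rot$lambda * Py) * PAePy),
      sum(Py * PAePy)), 2, 2)
    list(score = sc, AI = AI, Py = Py)
  }

  for (it in seq_len(max_iter)) {
    dv <- derivs(vg, ve)
    score <- dv$score
    AI <- dv$AI
    # active-set Newton: a component clipped at the floor with an outward
    # (negative) score stays fixed; the step solves the reduced AI system
    act <- !(c(vg, ve) <= floor_v * (1 + 1e-6) & score < 0)
    step <- rep(0, 2)
    st <- tryCatch(solve(AI[act, act, drop = FALSE], score[act]),
                   error = function(e) NULL)
    new <- NULL
    if (!is.null(st) && all(is.finite(st))) {
      step[act] <- st
      cand <- pmax(c(vg, ve) + step, floor_v)
      ll_cand <- greml_loglik_rot(cand[1], cand[2], rot)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) new <- list(v = cand, ll = ll_cand)
    }
    if (is.null(new)) {
      # EM-REML fallback: sigma_i^2 <- sigma_i^2 + sigma_i^4/n (y'PA_iPy - tr(PA_i))
      em <- c(vg + vg^2 / n * (2 * score[1]), ve + ve^2 / n * (2 * score[2]))
      cand <- pmax(em, floor_v)
      new <- list(v = cand, ll = greml_loglik_rot(cand[1], cand[2], rot))
    }
    delta_ll <- new$ll - ll
    vg <- new$v[1]; ve <- new$v[2]; ll <- new$ll
    traj <- rbind(traj, data.frame(iter = it, sigma2_g = vg, sigma2_e = ve,
                                   loglik = ll))
    at_floor <- c(vg, ve) <= floor_v * (1 + 1e-6)
    sc_free <- derivs(vg, ve)$score
    sc_free[at_floor & sc_free < 0] <- 0  # boundary: inward gradient only
    if (abs(delta_ll) < tol && sqrt(sum(sc_free^2)) < 1e-4) {
      converged <- TRUE
      break
    }
    if (abs(delta_ll) < tol) {
      # plateau while a small component creeps toward zero: snap it to the
      # boundary if that costs (numerically) nothing
      snap <- c(vg, ve)
      snap[snap < 1e-4 * vy] <- floor_v
      if (any(snap != c(vg, ve))) {
        ll_b <- greml_loglik_rot(snap[1], snap[2], rot)
        if (ll_b >= ll - 10 * tol) {
          vg <- snap[1]; ve <- snap[2]; ll <- ll_b
          converged <- TRUE
          break
        }
      }
    }
  }
  if (!converged)
    warning("AI-REML did not converge in ", max_iter, " iterations ",
            "(final loglik change ", signif(abs(delta_ll), 3), ")")

  h2 <- vg / (vg + ve)
  AI_inv <- tryCatch(solve(derivs(vg, ve)$AI), error = function(e) matrix(NA, 2, 2))
  gr <- c(ve, -vg) / (vg + ve)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% AI_inv %*% gr)))

  ll0 <- greml_loglik_rot(0, max(sum(qr.resid(qr(X), y)^2) / (n - p), floor_v),
                          rot)
  lrt <- max(0, 2 * (ll - ll0))
  pval <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(sigma2_g = vg, sigma2_e = ve, h2 = h2, se_h2 = se_h2,
                 loglik = ll, loglik_null = ll0, lrt = lrt, p = pval,
                 n_used = n, converged = converged, iterations = it,
                 trajectory = traj), class = "famvar_greml")
}

#' @export
print.famvar_greml <- function(x, ...) {
  cat("GREML fit (AI-REML)\n")
  cat(sprintf("  n = %d, sigma2_g = %.4f, sigma2_e = %.4f\n",
              x$n_used, x$sigma2_g, x$sigma2_e))
  cat(sprintf("  h2 = %.4f (s.e. = %.4f), LRT = %.3f, p = %.4g\n",
              x$h2, x$se_h2, x$lrt, x$p))
  invisible(x)
}
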