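test_that("with singleton families the fit collapses to plain NB regression", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 1500
  x <- rnorm(n)
  mu <- exp(0.6 + 0.3 * x)
  y <- rnbinom(n, size = 1 / 0.5, mu = mu)
  X <- cbind(1, x)
  fit <- fit_nb_glmm(y, X, 0, family_ids = seq_len(n), varpar_cov = TRUE)
  ref <- MASS::glm.nb(y ~ x)
  expect_lt(fit$sigma2_family, 0.01)  # no clustering to absorb
  se <- sqrt(diag(fit$varpar_cov))
  expect_lt(abs(fit$beta[1] - coef(ref)[1]), 3 * se[1] + 0.02)
  expect_lt(abs(fit$beta[2] - coef(ref)[2]), 3 * se[2] + 0.02)
  expect_equal(fit$alpha, 1 / ref$theta, tolerance = 0.1)
})

test_that("seven adaptive nodes all but exhaust the quadrature error", {
  d <- make_nb_fixture(30)
  X <- matrix(1, nrow(d), 1)
  fit <- fit_nb_glmm(d$y, X, d$offset_log, d$family_id, varpar_cov = FALSE)
  lls <- vapply(c(3, 7, 15, 51, 101), function(k)
    as.numeric(nb_glmm_loglik(fit$beta, fit$alpha, fit$sigma2_family,
                              d$y, X, d$offset_log, d$family_id, n_quad = k)),
    numeric(1))
  err <- abs(lls - lls[5])
  expect_lt(err[2], 1e-4)               # 7 vs 101 nodes
  expect_true(all(diff(err[-5]) <= 1e-10))  # monotone convergence 3->51
})

test_that("the NB likelihood approaches Poisson as alpha vanishes", {
  d <- make_nb_fixture(25, seed = 9)
  X <- matrix(1, nrow(d), 1)
  beta <- 0.8; s2 <- 0.3
  ll_nb <- nb_glmm_loglik(beta, 1e-8, s2, d$y, X, d$offset_log, d$family_id)
  ll_po <- nb_glmm_loglik(beta, 0, s2, d$y, X, d$offset_log, d$family_id)
  expect_lt(abs(as.numeric(ll_nb) - as.numeric(ll_po)), 1e-4)
})

test_that("parameters are recovered within 3 SE on simulated families", {
  d <- simulate_nb_families(1500, size = 3, beta0 = 0.5, alpha = 0.5,
                            sigma2 = 0.3, seed = 33)
  X <- matrix(1, nrow(d), 1)
  fit <- fit_nb_glmm(d$y, X, d$offset_log, d$family_id)
  se <- sqrt(diag(fit$varpar_cov))
  expect_lt(abs(fit$beta[1] - 0.5), 3 * se[1])
  expect_lt(abs(log(fit$alpha) - log(0.5)), 3 * se["log_alpha"])
  expect_lt(abs(log(fit$sigma2_family) - log(0.3)), 3 * se["log_sigma2"])
})

test_that("estimates are invariant to family relabelling and row order", {
  d <- make_nb_fixture(40, seed = 15)
  X <- matrix(1, nrow(d), 1)
  fit <- fit_nb_glmm(d$y, X, d$offset_log, d$family_id, varpar_cov = FALSE)
  set.seed(1)
  perm <- sample(nrow(d))
  relab <- paste0("fam", rev(d$family_id))[perm]
  fit2 <- fit_nb_glmm(d$y[perm], X[perm, , drop = FALSE], d$offset_log[perm],
                      relab, varpar_cov = FALSE)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-4)
  expect_equal(fit2$sigma2_family, fit$sigma2_family, tolerance = 1e-4)
})

test_that("the NB always dominates the nested Poisson in likelihood", {
  for (sd in c(2, 5)) {
    d <- simulate_nb_families(120, size = 2, beta0 = 0.6,
                              alpha = ifelse(sd == 2, 0, 0.8),
                              sigma2 = 0.2, seed = sd)
    X <- matrix(1, nrow(d), 1)
    cmp <- poisson_vs_nb_comparison(d$y, X, 0, d$family_id)
    expect_gte(cmp$fit_nb$loglik, cmp$fit_poisson$loglik - 1e-6)
    expect_true(cmp$lrt_overdispersion$p_value <= 0.5)
  }
  # strongly overdispersed data: the test must reject decisively
  d <- simulate_nb_families(1000, size = 2, beta0 = 0.6, alpha = 1,
                            sigma2 = 0.2, seed = 44)
  cmp <- poisson_vs_nb_comparison(d$y, matrix(1, nrow(d), 1), 0, d$family_id)
  expect_lt(cmp$lrt_overdispersion$p_value, 1e-6)
})

test_that("deviance residuals evaluate the stated formula", {
  mkfit <- function(y, beta0, alpha, offset = 0) {
    structure(list(beta = beta0, alpha = alpha, X = matrix(1, length(y), 1),
                   offset_log = rep(offset, length(y)), y = y,
                   family_ids = as.character(seq_along(y)),
                   modes = numeric(length(y)), poisson = FALSE),
              class = "famvar_nbglmm")
  }
  # perfect fit: residual 0
  expect_equal(nb_deviance_residuals(mkfit(2, log(2), 0.5)), 0)
  # documented spot value: y = 5, m = 2, alpha = 0.5
  d <- nb_deviance_residuals(mkfit(5, log(2), 0.5))
  expect_equal(d, 1.1525, tolerance = 1e-4)
  expect_gt(d, 0)
  # y = 0 uses the y log(y/m) := 0 convention
  d0 <- nb_deviance_residuals(mkfit(0, log(2), 0.5))
  expect_lt(d0, 0)
  expect_true(is.finite(d0))
  # alpha ~ 0 reduces to the Poisson deviance residual
  dp <- nb_deviance_residuals(mkfit(5, log(2), 0))
  expect_equal(dp, sign(3) * sqrt(2 * (5 * log(5 / 2) - 3)), tolerance = 1e-10)

  # refitting the mean structure reduces the total squared deviance
  set.seed(10)
  x <- rnorm(400)
  y <- rnbinom(400, size = 2, mu = exp(1 + 0.6 * x))
  f_cov <- fit_nb_glmm(y, cbind(1, x), 0, seq_along(y), no_random = TRUE,
                       varpar_cov = FALSE)
  f_int <- fit_nb_glmm(y, matrix(1, 400, 1), 0, seq_along(y),
                       no_random = TRUE, varpar_cov = FALSE)
  expect_lt(sum(nb_deviance_residuals(f_cov)^2),
            sum(nb_deviance_residuals(f_int)^2))
})

test_that("degenerate count inputs are rejected", {
  expect_error(fit_nb_glmm(c(-1, 2, 3), matrix(1, 3, 1), 0, 1:3),
               "non-negative")
  expect_error(fit_nb_glmm(rep(3L, 10), matrix(1, 10, 1), 0, rep(1:5, 2)),
               "identical")
  expect_error(fit_nb_glmm(c(1, 2, 3), matrix(1, 3, 1), c(0, Inf, 0), 1:3),
               "finite")
})
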