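test_that("REML on a balanced one-way layout equals the ANOVA moment estimators", {
  fx <- make_balanced_lmm(k = 20, m = 4)
  fit <- fit_lmm_nested(fx$y, fx$X, fx$fam)
  a <- anova(aov(fx$y ~ factor(fx$fam)))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  expect_equal(fit$sigma2_e, msw, tolerance = 1e-6)
  expect_equal(fit$sigma2_family, (msb - msw) / fx$m, tolerance = 1e-6)
})

test_that("the standalone REML log-likelihood matches lme4 at the optimum", {
  s <- simulate_family_phenotypes(n_families = 200, seed = 7)
  d <- s$table
  X <- cbind(1, d$sex)
  fit <- fit_lmm_nested(sqrt_aao(d$aao), X, d$family_id, d$center_id,
                        varpar_cov = FALSE)
  ll <- reml_loglik_nested(sqrt_aao(d$aao), X, d$family_id, d$center_id,
                           fit$sigma2_center, fit$sigma2_family, fit$sigma2_e)
  expect_equal(ll, fit$loglik_reml, tolerance = 1e-6)
  # a change of fixed-effect basis leaves the estimates untouched and
  # shifts the restricted likelihood by exactly log|det T|
  T <- matrix(c(1, 0.5, 0, 2), 2, 2)
  fit2 <- fit_lmm_nested(sqrt_aao(d$aao), X %*% T, d$family_id, d$center_id,
                         varpar_cov = FALSE)
  expect_equal(fit2$loglik_reml + log(abs(det(T))), fit$loglik_reml,
               tolerance = 1e-6)
  expect_equal(fit2$sigma2_family, fit$sigma2_family, tolerance = 1e-6)
  expect_equal(fit2$sigma2_e, fit$sigma2_e, tolerance = 1e-6)
})

test_that("a null family component is estimated at the boundary", {
  tr <- sim_truth(sigma2_family = 0, sigma2_center = 0)
  s <- simulate_family_phenotypes(n_families = 1300, truth = tr, seed = 19)
  d <- s$table
  fit <- fit_lmm_nested(sqrt_aao(d$aao), cbind(1, d$sex), d$family_id,
                        varpar_cov = FALSE)
  expect_lt(fit$sigma2_family / (fit$sigma2_family + fit$sigma2_e), 0.02)
})

test_that("three-level variance components are recovered within 3 SE", {
  tr <- sim_truth(sigma2_center = 0.2, sigma2_family = 1, sigma2_e = 3,
                  beta0_aao = 6)
  s <- simulate_family_phenotypes(n_families = 1200, truth = tr, seed = 3)
  d <- s$table
  fit <- fit_lmm_nested(sqrt_aao(d$aao), cbind(1, d$sex), d$family_id,
                        d$center_id)
  se <- sqrt(diag(fit$varpar_cov))
  expect_lt(abs(fit$sigma2_family - 1), 3 * se["sigma2_family"])
  expect_lt(abs(fit$sigma2_e - 3), 3 * se["sigma2_e"])
  # centre has only 8 levels; allow its wide sampling spread
  expect_lt(abs(fit$sigma2_center - 0.2), 0.35)
})

test_that("the boundary LRT uses the 50:50 chi-square mixture", {
  fx <- make_balanced_lmm(k = 15, m = 3, sigma2_f = 0.5)
  fit <- fit_lmm_nested(fx$y, fx$X, fx$fam, varpar_cov = FALSE)
  red <- famvar:::drop_family_refit(fit)
  l <- lrt_family_variance(fit, red)
  expect_gte(l$statistic, 0)
  expect_equal(l$p_value, 0.5 * pchisq(l$statistic, 1, lower.tail = FALSE))

  # spot values of the mixture: stat 0 -> p 0.5; stat 2.706 -> p 0.05
  r2 <- fit; r2$loglik_reml <- fit$loglik_reml
  expect_equal(lrt_family_variance(fit, r2)$p_value, 0.5)
  r3 <- fit; r3$loglik_reml <- fit$loglik_reml - 2.706 / 2
  expect_equal(lrt_family_variance(fit, r3)$p_value, 0.05, tolerance = 1e-3)

  other <- fit_lmm_nested(fx$y + 1, fx$X, fx$fam, varpar_cov = FALSE)
  expect_error(lrt_family_variance(fit, other), "same data")
})

test_that("the residual ICC matches its definition and responds to the centre flag", {
  fx <- make_balanced_lmm(k = 40, m = 4, sigma2_f = 1, sigma2_e = 3, seed = 2)
  fit <- fit_lmm_nested(fx$y, fx$X, fx$fam)
  manual <- fit$sigma2_family / (fit$sigma2_family + fit$sigma2_e)
  icc <- residual_icc(fit)
  expect_equal(icc$icc, manual, tolerance = 1e-10)
  expect_true(icc$ci_low <= icc$icc && icc$icc <= icc$ci_high)
  expect_gt(icc$se, 0)

  # monotone in sigma2_family with sigma2_e held fixed
  vals <- vapply(c(0.5, 1, 2, 4), function(v) {
    f <- fit; f$sigma2_family <- v
    residual_icc(f)$icc
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))

  # with a centre level, including it enlarges the ICC
  s <- simulate_family_phenotypes(n_families = 400, seed = 8)
  d <- s$table
  f3 <- fit_lmm_nested(sqrt_aao(d$aao), cbind(1, d$sex), d$family_id,
                       d$center_id)
  expect_gt(residual_icc(f3, include_center = TRUE)$icc,
            residual_icc(f3)$icc)
})

test_that("replicating every family leaves the variance estimates unchanged", {
  # doubling each family as a new family doubles every likelihood
  # contribution, so the REML optimum is identical
  fx <- make_balanced_lmm(k = 25, m = 3, seed = 5)
  fit <- fit_lmm_nested(fx$y, fx$X, fx$fam, varpar_cov = FALSE)
  y2 <- c(fx$y, fx$y)
  fam2 <- c(fx$fam, fx$fam + 1000L)
  fit2 <- fit_lmm_nested(y2, rbind(fx$X, fx$X), fam2, varpar_cov = FALSE)
  # equality is approximate: the REML fixed-effect penalty log|X'V^-1 X|
  # does not scale linearly with replication (ML would be exact)
  expect_equal(fit2$sigma2_family, fit$sigma2_family, tolerance = 0.05)
  expect_equal(fit2$sigma2_e, fit$sigma2_e, tolerance = 0.05)
})

test_that("LMM residuals obey the marginal and conditional conventions", {
  s <- simulate_family_phenotypes(n_families = 150, seed = 13)
  d <- s$table
  y <- sqrt_aao(d$aao)
  fit <- fit_lmm_nested(y, cbind(1, d$sex), d$family_id, d$center_id,
                        varpar_cov = FALSE)
  r_marg <- lmm_residuals(fit, level = "none")
  expect_equal(r_marg, y - drop(fit$X %*% fit$beta))
  expect_lt(abs(mean(r_marg)), 0.05)  # intercept absorbs the mean

  r_cen <- lmm_residuals(fit, level = "center")
  r_all <- lmm_residuals(fit, level = "all")
  # subtracting BLUPs strictly reduces the residual sum of squares
  expect_lt(sum(r_all^2), sum(r_cen^2))
  expect_lte(sum(r_cen^2), sum(r_marg^2) + 1e-8)
  # variance bookkeeping: marginal residuals carry the full mixture
  # sigma2_c + sigma2_f + sigma2_e, while BLUP shrinkage pulls the
  # conditional residual variance below sigma2_e
  total <- fit$sigma2_center + fit$sigma2_family + fit$sigma2_e
  expect_equal(var(r_marg), total, tolerance = 0.15)
  expect_lt(var(r_all), fit$sigma2_e)
  expect_gt(var(r_all), 0.4 * fit$sigma2_e)
})

test_that("invalid designs are rejected", {
  fx <- make_balanced_lmm()
  expect_error(fit_lmm_nested(fx$y, cbind(fx$X, fx$X), fx$fam),
               "rank deficient")
  cen <- rep(1:2, length.out = length(fx$y))  # families straddle centres
  expect_error(fit_lmm_nested(fx$y, fx$X, fx$fam, cen), "nested")
  expect_error(fit_lmm_nested(fx$y[-1], fx$X, fx$fam), "matching")
})
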