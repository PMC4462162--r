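test_that("family tables satisfy their structural invariants and are reproducible", {
  s1 <- simulate_family_phenotypes(n_families = 300, seed = 5)
  s2 <- simulate_family_phenotypes(n_families = 300, seed = 5)
  expect_identical(s1$table, s2$table)
  s3 <- simulate_family_phenotypes(n_families = 300, seed = 6)
  expect_false(identical(s1$table, s3$table))

  d <- s1$table
  expect_true(all(d$aao <= d$age + 1e-8))
  expect_true(all(d$age - d$aao >= 0))
  sizes <- table(d$family_id)
  expect_true(all(sizes >= 2 & sizes <= 5))
  expect_true(all(tapply(d$center_id, d$family_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(d$episode_count >= 1))  # recurrent ascertainment
  expect_true(all(d$aao >= 5 - 1e-8))

  # default configuration: 691 families of 2-5 siblings
  s <- simulate_family_phenotypes(seed = 1)
  expect_gte(nrow(s$table), 1382)
  expect_lte(nrow(s$table), 3455)

  expect_error(simulate_family_phenotypes(n_families = 1), "at least 2")
  expect_error(simulate_family_phenotypes(300, size_weights = c(1, 1, 1, 1)),
               "sum to 1")
  expect_error(sim_truth(sigma2_family = -1), "non-negative")
})

test_that("zero family variance leaves no between-family signal in sqrt(aao)", {
  tr <- sim_truth(sigma2_family = 0, sigma2_center = 0)
  s <- simulate_family_phenotypes(n_families = 2000, truth = tr, seed = 9)
  d <- s$table
  res <- resid(lm(sqrt(d$aao) ~ d$sex))
  icc <- empirical_icc_counts(res - min(res) + 1e-9, d$family_id)$icc
  # pairwise correlation of residuals across siblings ~ 0 (the estimator is
  # location-invariant so the shift above is harmless)
  expect_lt(abs(icc), 0.04)
})

test_that("the generator reproduces the target sibling correlation of sqrt(aao)", {
  # moment-estimator oracle on a large sample: true conditional-on-centre
  # ratio is 0.278
  s <- simulate_family_phenotypes(n_families = 5000, truth = sim_truth(),
                                  seed = 31)
  d <- s$table
  res <- resid(lm(sqrt(d$aao) ~ d$sex + factor(d$center_id)))
  icc <- empirical_icc_counts(res - min(res) + 1e-9, d$family_id)$icc
  expect_equal(icc, 0.278, tolerance = 0.035)
  expect_equal(s$truth$icc_aao, 0.278, tolerance = 1e-12)
})

test_that("NB generator matches the closed-form marginal moments", {
  # E(Y) = mu, Var(Y) = mu + alpha mu^2 e^{s2} + mu^2 (e^{s2} - 1)
  beta0 <- log(2) - 0.05; s2 <- 0.1; a <- 0.5
  d <- simulate_nb_families(2e5, size = 1, beta0 = beta0, alpha = a,
                            sigma2 = s2, seed = 17)
  mu <- exp(beta0 + s2 / 2)
  vtot <- mu + a * mu^2 * exp(s2) + mu^2 * (exp(s2) - 1)
  expect_equal(mean(d$y), mu, tolerance = 0.02)
  expect_equal(var(d$y), vtot, tolerance = 0.05)
  # family effect is shared: both siblings see the same latent intercept
  d2 <- simulate_nb_families(200, size = 2, beta0 = 0, alpha = 0,
                             sigma2 = 4, seed = 3)
  y <- matrix(d2$y, ncol = 2, byrow = TRUE)
  expect_gt(cor(y[, 1], y[, 2]), 0.4)
})

test_that("genotype panels respect allele-frequency bounds and planted heritability", {
  sim <- simulate_genotype_phenotype(5000, 60, maf_range = c(0.1, 0.4),
                                     h2_snp = 0.5, seed = 23)
  phat <- colMeans(sim$genotypes$codes) / 2
  p0 <- sim$truth$maf
  se <- sqrt(p0 * (1 - p0) / (2 * 5000))
  expect_true(all(abs(phat - p0) < 5 * se))
  expect_true(all(phat > 0.05 & phat < 0.45))

  # realised genetic variance share close to target
  expect_equal(sim$truth$h2_snp_realized, 0.5, tolerance = 0.05)
  g <- sim$truth$genetic_values
  expect_equal(var(g) / var(sim$phenotype), 0.5, tolerance = 0.06)

  # null architecture: phenotype independent of genotypes
  sim0 <- simulate_genotype_phenotype(500, 100, h2_snp = 0, seed = 2)
  expect_equal(sim0$truth$h2_snp_realized, 0)
  expect_identical(simulate_genotype_phenotype(100, 50, seed = 4)$genotypes$codes,
                   simulate_genotype_phenotype(100, 50, seed = 4)$genotypes$codes)

  expect_error(simulate_genotype_phenotype(1, 10), "at least 2")
  expect_error(simulate_genotype_phenotype(10, 10, maf_range = c(0.6, 0.7)),
               "interval")
  expect_error(simulate_genotype_phenotype(10, 10, n_causal = 20), "exceed")
})

test_that("phenotype tables round-trip through the TSV format", {
  s <- simulate_family_phenotypes(n_families = 50, seed = 12)
  path <- tempfile(fileext = ".tsv")
  write_phenotype_table(s$table, path)
  back <- read_phenotype_table(path)
  expect_equal(back, s$table[names(back)])
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:7], c("subject_id", "family_id", "center_id",
                                  "sex", "age", "aao", "episode_count"))
  # structural validation catches corrupted tables
  bad <- s$table
  bad$aao[1] <- bad$age[1] + 5
  expect_error(famvar:::check_phenotype_table(bad), "aao > age")
})
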