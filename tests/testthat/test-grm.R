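test_that("the GRM formula matches hand evaluation on tiny inputs", {
  g <- famvar:::new_genotypes(
    ids = c("a", "b"),
    snps = data.frame(id = "s1", chrom = 1, cm = 0, bp = 1, A1 = "A", A2 = "G"),
    codes = matrix(c(0L, 2L), 2, 1))
  A <- compute_grm(g, maf_min = 0.01)$values
  expect_equal(unname(A), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # an individual sitting exactly at 2p on every SNP relates to no one
  codes <- rbind(c(0L, 2L), c(2L, 0L), c(1L, 1L))  # p = 0.5 both SNPs
  g3 <- famvar:::new_genotypes(
    ids = c("a", "b", "c"),
    snps = data.frame(id = c("s1", "s2"), chrom = 1, cm = 0, bp = 1:2,
                      A1 = "A", A2 = "G"),
    codes = codes)
  A3 <- compute_grm(g3, maf_min = 0.01)$values
  expect_equal(unname(A3[3, 1:2]), c(0, 0), tolerance = 1e-12)
})

test_that("GRM moments under HWE match independence theory", {
  sim <- simulate_genotype_phenotype(1000, 5000, h2_snp = 0, seed = 14)
  grm <- compute_grm(sim$genotypes, maf_min = 0.01)
  dg <- diag(grm$values)
  expect_lt(abs(mean(dg) - 1), 3 * sd(dg) / sqrt(1000))
  off <- grm$values[upper.tri(grm$values)]
  expect_equal(var(off), 1 / grm$n_snps_used, tolerance = 0.05)
  expect_equal(grm$values, t(grm$values))
  expect_true(all(grm$pair_n <= 5000))
})

test_that("MAF filtering and missingness bookkeeping are exact", {
  set.seed(3)
  rare <- c(1L, rep(0L, 199))  # allele frequency 1/400, below the cutoff
  codes <- cbind(rbinom(200, 2, 0.3), rare, rbinom(200, 2, 0.25))
  codes[1:10, 1] <- NA
  g <- famvar:::new_genotypes(
    ids = sprintf("i%03d", 1:200),
    snps = data.frame(id = paste0("s", 1:3), chrom = 1, cm = 0, bp = 1:3,
                      A1 = "A", A2 = "G"),
    codes = codes)
  grm <- compute_grm(g, maf_min = 0.01)
  expect_equal(grm$n_snps_excluded, 1L)  # the near-monomorphic SNP
  expect_equal(grm$n_snps_used, 2L)
  # pairs with a missing genotype use fewer SNPs
  expect_equal(grm$pair_n[1, 2], 1)
  expect_equal(grm$pair_n[100, 101], 2)
  expect_error(compute_grm(g, maf_min = 0.49), "MAF")
})

test_that("greedy pruning removes the documented individuals", {
  # no pair above the cutoff: everyone retained
  g0 <- make_noise_grm(30, n_pairs = 0, seed = 2)
  expect_identical(prune_relatedness(g0, 0.025), g0$ids)

  # exactly one pair above the cutoff: exactly one individual removed
  g1 <- make_noise_grm(30, n_pairs = 1, seed = 3)
  kept <- prune_relatedness(g1, 0.025)
  expect_equal(length(kept), 29L)
  expect_false(g1$ids[1] %in% kept)  # first of the tied pair goes

  # planted sibling blocks: one member per block survives, and the result
  # matches the exhaustive maximum-independent-set size on <= 12 ids
  g2 <- make_noise_grm(12, n_pairs = 4, seed = 4)
  kept2 <- prune_relatedness(g2, 0.025)
  expect_equal(length(kept2), 8L)
  A <- g2$values; diag(A) <- 0
  best <- 0L
  for (mask in 0:(2^12 - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:11)) > 0)
    if (length(idx) <= best) next
    if (all(A[idx, idx] <= 0.025)) best <- length(idx)
  }
  expect_equal(length(kept2), best)
  sub <- g2$values[match(kept2, g2$ids), match(kept2, g2$ids)]
  diag(sub) <- 0
  expect_true(all(sub <= 0.025))

  allrel <- famvar:::new_grm(c("a", "b"), matrix(c(1, 0.5, 0.5, 1), 2),
                             matrix(100, 2, 2))
  expect_error(prune_relatedness(allrel, 0.4), NA)  # one survivor is fine
  expect_error(prune_relatedness(allrel, 0), "cutoff > 0")
})

test_that("GRM principal components recover planted structure", {
  # identity GRM: any orthonormal basis is acceptable
  gI <- famvar:::new_grm(sprintf("i%02d", 1:20), diag(20), matrix(1, 20, 20))
  sc <- grm_pca(gI, k = 5)
  expect_equal(unname(crossprod(sc)), diag(5), tolerance = 1e-8)

  # two subpopulations with shifted allele frequencies: PC1 separates them
  set.seed(8)
  n <- 120; m <- 800
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5); p2 <- pmin(0.95, p1 + 0.3)
  codes <- t(vapply(pop, function(g)
    rbinom(m, 2L, if (g == 0) p1 else p2), integer(m)))
  gP <- famvar:::new_genotypes(
    ids = sprintf("i%03d", 1:n),
    snps = data.frame(id = paste0("s", 1:m), chrom = 1, cm = 0, bp = 1:m,
                      A1 = "A", A2 = "G"),
    codes = codes)
  sc <- grm_pca(compute_grm(gP), k = 2)
  cls <- sc[, 1] > median(sc[, 1])
  acc <- max(mean(cls == (pop == 1)), mean(cls == (pop == 0)))
  expect_gt(acc, 0.99)

  # scores are orthogonal and the sign convention is deterministic
  sc2 <- grm_pca(compute_grm(gP), k = 2)
  expect_identical(sc, sc2)
  G <- crossprod(sc)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(grm_pca(gI, k = 20), "smaller")
})
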