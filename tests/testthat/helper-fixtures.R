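# Shared fixture builders; everything is generated in code under fixed seeds.

# Balanced one-way layout: k families of equal size m, no centre level.
make_balanced_lmm <- function(k = 20, m = 4, sigma2_f = 0.8, sigma2_e = 1,
                              seed = 42) {
  set.seed(seed)
  fam <- rep(seq_len(k), each = m)
  y <- rnorm(k, 0, sqrt(sigma2_f))[fam] + rnorm(k * m, 0, sqrt(sigma2_e))
  list(y = y, X = matrix(1, k * m, 1), fam = fam, k = k, m = m)
}

# Small NB mixed-model fixture for quadrature checks (30 families).
make_nb_fixture <- function(n_fam = 30, seed = 7) {
  simulate_nb_families(n_fam, size = 3, beta0 = 0.8, alpha = 0.4,
                       sigma2 = 0.35, seed = seed)
}

# Hand-built PLINK bed fileset: 4 individuals x 2 SNPs with known bytes.
# SNP1 A1 counts (2, 1, 0, NA) -> two-bit fields 00 10 11 01 -> byte 120;
# SNP2 all heterozygous -> fields 10x4 -> byte 170.
write_hand_bed <- function(dir) {
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 120, 170)), paste0(prefix, ".bed"))
  writeLines(c("1 snp1 0 100 A G", "1 snp2 0 200 C T"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("F%d I%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  prefix
}

# Synthetic GRM with array-scale noise (off-diagonal sd as at ~0.43M SNPs)
# and optional planted relative pairs at a given relatedness.
make_noise_grm <- function(n, n_pairs = 0, relatedness = 0.5, noise_sd = 0.0015,
                           seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n, 0, noise_sd), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  if (n_pairs > 0) {
    stopifnot(2 * n_pairs <= n)
    for (k in seq_len(n_pairs)) {
      i <- 2 * k - 1; j <- 2 * k
      A[i, j] <- A[j, i] <- relatedness
    }
  }
  famvar:::new_grm(sprintf("I%03d", seq_len(n)), A, matrix(430000, n, n))
}
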