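## Synthetic genotype-phenotype panels with a known polygenic architecture.

#' Simulate a genotype panel and a polygenic phenotype
#'
#' Draws `n_snp` independent SNPs under Hardy-Weinberg equilibrium at allele
#' frequencies sampled uniformly from `maf_range`, picks `n_causal` causal
#' SNPs, builds a polygenic score from standardised causal genotypes scaled to
#' variance `h2_snp`, and adds Gaussian noise of variance `1 - h2_snp`.
#'
#' @param n_ind Number of individuals (>= 2).
#' @param n_snp Number of SNPs.
#' @param maf_range Interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn (default `c(0.05, 0.5)`).
#' @param h2_snp Target SNP heritability in \[0, 1).
#' @param n_causal Number of causal SNPs (default `min(n_snp, 500)`).
#' @param seed Integer seed.
#' @return List with `genotypes` (a `famvar_genotypes` object: `ids`, `snps`
#'   metadata, `codes` N x M matrix of allele counts, `freqs`), `phenotype`
#'   (length-N vector), and `truth` (target and realised h2, causal indices,
#'   genetic values).
#' @export
simulate_genotype_phenotype <- function(n_ind, n_snp, maf_range = c(0.05, 0.5),
                                        h2_snp = 0.5,
                                        n_causal = min(n_snp, 500L),
                                        seed = 1) {
  if (n_ind < 2) stop("need at least 2 individuals")
  if (n_causal > n_snp) stop("n_causal cannot exceed n_snp")
  if (h2_snp < 0 || h2_snp >= 1) stop("h2_snp must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")

  set.seed(child_seed(seed, "genotypes"))
  p <- stats::runif(n_snp, maf_range[1], maf_range[2])
  codes <- vapply(p, function(pi) stats::rbinom(n_ind, 2L, pi),
                  integer(n_ind))
  storage.mode(codes) <- "integer"

  causal <- sort(sample.int(n_snp, n_causal))
  u <- stats::rnorm(n_causal)
  # standardise causal genotypes at the generating frequencies
  W <- sweep(codes[, causal, drop = FALSE], 2L, 2 * p[causal], "-")
  W <- sweep(W, 2L, sqrt(2 * p[causal] * (1 - p[causal])), "/")
  g <- as.vector(W %*% u)
  if (h2_snp > 0 && stats::sd(g) > 0) {
    g <- g * sqrt(h2_snp) / stats::sd(g)
  } else {
    g <- rep(0, n_ind)
  }
  e <- stats::rnorm(n_ind, 0, sqrt(1 - h2_snp))
  y <- g + e

  ids <- sprintf("I%05d", seq_len(n_ind))
  geno <- new_genotypes(
    ids = ids,
    snps = data.frame(id = sprintf("snp%05d", seq_len(n_snp)),
                      chrom = 1L, cm = 0, bp = seq_len(n_snp) * 1000L,
                      A1 = "A", A2 = "G", stringsAsFactors = FALSE),
    codes = codes)
  vg <- stats::var(g)
  truth <- list(h2_snp_target = h2_snp,
                h2_snp_realized = vg / (vg + stats::var(e)),
                causal = causal, genetic_values = g, maf = p)
  list(genotypes = geno, phenotype = y, truth = truth)
}

# Constructor for the genotype container used across the GREML track.
new_genotypes <- function(ids, snps, codes) {
  stopifnot(nrow(codes) == length(ids), ncol(codes) == nrow(snps))
  freqs <- colMeans(codes, na.rm = TRUE) / 2
  structure(list(ids = ids, snps = snps, codes = codes, freqs = freqs),
            class = "famvar_genotypes")
}

#' @export
print.famvar_genotypes <- function(x, ...) {
  cat("Genotype panel:", length(x$ids), "individuals x", nrow(x$snps),
      "SNPs\n")
  invisible(x)
}
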