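## Genetic relationship matrix: construction, relatedness pruning, PCA.

#' Compute the genetic relationship matrix
#'
#' GCTA-style GRM: `A_jk = (1/M_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))` over SNPs non-missing in both individuals, with `p_i`
#' the sample allele frequency.  SNPs with minor allele frequency below
#' `maf_min` are excluded before standardisation.
#'
#' @param g A `famvar_genotypes` object (see [simulate_genotype_phenotype()]
#'   or [read_plink_bed()]).
#' @param maf_min Minor-allele-frequency cutoff (default 0.01).
#' @return A `famvar_grm` object: `ids`, `values` (full symmetric N x N
#'   matrix), `pair_n` (per-pair SNP counts), `n_snps_used`,
#'   `n_snps_excluded`.
#' @export
compute_grm <- function(g, maf_min = 0.01) {
  stopifnot(inherits(g, "famvar_genotypes"))
  n <- length(g$ids)
  if (n < 2) stop("need at least 2 individuals")
  p <- colMeans(g$codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(maf) & maf >= maf_min & maf > 0
  if (!any(keep)) stop("no SNPs pass the MAF filter")
  codes <- g$codes[, keep, drop = FALSE]
  p <- p[keep]
  M <- ncol(codes)

  Z <- sweep(codes, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  if (anyNA(Z)) {
    obs <- !is.na(Z)
    Z[!obs] <- 0
    pair_n <- tcrossprod(obs * 1)
    A <- tcrossprod(Z) / pair_n
  } else {
    A <- tcrossprod(Z) / M
    pair_n <- matrix(M, n, n)
  }
  dimnames(A) <- list(g$ids, g$ids)
  structure(list(ids = g$ids, values = A, pair_n = pair_n,
                 n_snps_used = M, n_snps_excluded = sum(!keep)),
            class = "famvar_grm")
}

# Internal constructor used by the GRM reader.
new_grm <- function(ids, values, pair_n) {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, pair_n = pair_n,
                 n_snps_used = max(pair_n), n_snps_excluded = NA_integer_),
            class = "famvar_grm")
}

#' @export
print.famvar_grm <- function(x, ...) {
  cat("GRM:", length(x$ids), "individuals,", x$n_snps_used, "SNPs\n")
  cat(sprintf("  mean diagonal %.4f, off-diagonal sd %.5f\n",
              mean(diag(x$values)),
              stats::sd(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Greedy relatedness pruning
#'
#' Removes individuals until no pair has relatedness above `cutoff`: while
#' any off-diagonal entry exceeds the cutoff, the individual involved in the
#' most such pairs is dropped (ties broken by input order).
#'
#' @param grm A `famvar_grm` object.
#' @param cutoff Relatedness threshold (default 0.025).
#' @return Character vector of retained ids, in input order.
#' @export
prune_relatedness <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "famvar_grm"), cutoff > 0)
  A <- grm$values
  diag(A) <- 0
  active <- rep(TRUE, nrow(A))
  over <- A > cutoff
  deg <- rowSums(over)
  while (any(deg[active] > 0)) {
    cand <- which(active & deg == max(deg[active]))[1L]
    active[cand] <- FALSE
    hit <- which(over[cand, ] & active)
    deg[hit] <- deg[hit] - 1L
    deg[cand] <- 0L
  }
  if (!any(active)) stop("all individuals removed by relatedness pruning")
  grm$ids[active]
}

#' Principal components of the GRM
#'
#' Top-`k` eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param grm A `famvar_grm` object.
#' @param k Number of components (default 10; must be < N).
#' @return N x k matrix of component scores (rownames are ids).
#' @export
grm_pca <- function(grm, k = 10) {
  stopifnot(inherits(grm, "famvar_grm"))
  n <- length(grm$ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  e <- eigen(grm$values, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  scores <- U %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(scores) <- grm$ids
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  scores
}

# Subset a GRM to a set of ids (order preserved as given).
subset_grm <- function(grm, ids) {
  idx <- match(ids, grm$ids)
  if (anyNA(idx)) stop("unknown ids in GRM subset")
  out <- grm
  out$ids <- grm$ids[idx]
  out$values <- grm$values[idx, idx, drop = FALSE]
  out$pair_n <- grm$pair_n[idx, idx, drop = FALSE]
  out
}
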