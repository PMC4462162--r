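## GCTA GRM binary triplet IO: <prefix>.grm.bin holds the lower triangle
## including the diagonal as single-precision floats, row-major by
## individual; <prefix>.grm.N.bin the per-pair SNP counts in the same order;
## <prefix>.grm.id two whitespace-separated id fields (FID IID) per line.

#' Write a GRM in GCTA binary format
#'
#' @param grm A `famvar_grm` object.
#' @param path_prefix Output path without the `.grm.*` extensions.
#' @return `path_prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, path_prefix) {
  stopifnot(inherits(grm, "famvar_grm"))
  n <- length(grm$ids)
  lower <- grm$values[upper.tri(grm$values, diag = TRUE)]
  # upper.tri of the symmetric matrix, column-major, enumerates pairs
  # (1,1), (1,2), (2,2), (1,3), ... == GCTA's row-major lower triangle
  lower_n <- grm$pair_n[upper.tri(grm$pair_n, diag = TRUE)]
  con <- file(paste0(path_prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L)
  close(con)
  con <- file(paste0(path_prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(lower_n), con, size = 4L)
  close(con)
  fid <- sub("_.*$", "", grm$ids)
  iid <- sub("^[^_]*_", "", grm$ids)
  if (any(fid == grm$ids)) { fid <- grm$ids; iid <- grm$ids }
  utils::write.table(data.frame(fid, iid), paste0(path_prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path_prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param path_prefix Path without the `.grm.*` extensions.
#' @return A `famvar_grm` object (values at the stored single precision).
#' @export
read_grm_gcta <- function(path_prefix) {
  idf <- paste0(path_prefix, ".grm.id")
  binf <- paste0(path_prefix, ".grm.bin")
  nf <- paste0(path_prefix, ".grm.N.bin")
  for (f in c(idf, binf, nf)) if (!file.exists(f)) stop("missing file: ", f)
  id <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(id) != 2L) stop("GRM id file must have two fields per line")
  n <- nrow(id)
  npair <- n * (n + 1) / 2
  vals <- readBin(binf, what = "numeric", n = npair + 1, size = 4L)
  cnts <- readBin(nf, what = "numeric", n = npair + 1, size = 4L)
  if (length(vals) != npair || length(cnts) != npair)
    stop("GRM binary length does not match id count (truncated or id mismatch)")
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A))
  Np <- matrix(0, n, n)
  Np[upper.tri(Np, diag = TRUE)] <- cnts
  Np <- Np + t(Np) - diag(diag(Np))
  ids <- if (all(id[[1]] == id[[2]])) id[[2]] else paste(id[[1]], id[[2]], sep = "_")
  new_grm(ids = ids, values = A, pair_n = Np)
}
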