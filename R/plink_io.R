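## PLINK bed/bim/fam binary genotype IO (variant-major bed, magic bytes
## 0x6c 0x1b 0x01).  Two-bit codes per individual, packed four to a byte,
## least-significant pair first: 00 = homozygous A1 (allele count 2),
## 10 = heterozygous (1), 11 = homozygous A2 (0), 01 = missing.

#' Read a PLINK bed/bim/fam fileset
#'
#' @param path_prefix Path without extension; `<prefix>.bed`,
#'   `<prefix>.bim`, `<prefix>.fam` must all exist.
#' @return A `famvar_genotypes` object (`codes` counts the A1 allele).
#' @export
read_plink_bed <- function(path_prefix) {
  bed <- paste0(path_prefix, ".bed")
  bim <- paste0(path_prefix, ".bim")
  fam <- paste0(path_prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)

  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pid", "mid",
                                            "sex", "pheno"))
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "bp",
                                            "A1", "A2"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3 + m * bytes_per_snp + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad magic bytes: not a PLINK bed file")
  if (raw[3] != as.raw(0x01))
    stop("only variant-major bed files are supported")
  if (length(raw) != 3 + m * bytes_per_snp)
    stop("truncated bed file: expected ", 3 + m * bytes_per_snp,
         " bytes, found ", length(raw))

  # decode all two-bit fields at once via a 256 x 4 lookup table
  two_bit <- t(vapply(0:255, function(b)
    bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L), integer(4)))
  code_map <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11 -> A1 count
  body <- as.integer(raw[-(1:3)]) + 1L
  fields <- matrix(t(two_bit[body, , drop = FALSE]), nrow = 4 * bytes_per_snp)
  codes <- matrix(code_map[fields[seq_len(n), , drop = FALSE] + 1L],
                  nrow = n, ncol = m)
  ids <- if (all(fam_df$fid == fam_df$iid)) fam_df$iid
         else paste(fam_df$fid, fam_df$iid, sep = "_")
  new_genotypes(ids = ids,
                snps = bim_df[c("id", "chrom", "cm", "bp", "A1", "A2")],
                codes = codes)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' @param g A `famvar_genotypes` object.
#' @param path_prefix Output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_plink_bed <- function(g, path_prefix) {
  stopifnot(inherits(g, "famvar_genotypes"))
  n <- length(g$ids); m <- nrow(g$snps)
  ids <- g$ids
  fid <- sub("_.*$", "", ids)
  iid <- sub("^[^_]*_", "", ids)
  if (any(fid == ids)) { fid <- ids; iid <- ids }  # ids without FID_IID form
  utils::write.table(
    data.frame(fid, iid, 0L, 0L, 0L, -9L),
    paste0(path_prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    g$snps[c("chrom", "id", "cm", "bp", "A1", "A2")],
    paste0(path_prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  rev_map <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # A1 count -> two-bit code
  codes <- g$codes
  fields <- matrix(3L, nrow = 4 * bytes_per_snp, ncol = m)  # pad with "0 copies"
  fld <- rev_map[as.character(codes)]
  fld[is.na(fld)] <- 1L  # missing
  fields[seq_len(n), ] <- matrix(fld, nrow = n)
  if (pad > 0) fields[(n + 1):(4 * bytes_per_snp), ] <- 0L  # zero-bit padding
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    v <- fields[, j]
    byte <- v[c(TRUE, FALSE, FALSE, FALSE)] +
      4L * v[c(FALSE, TRUE, FALSE, FALSE)] +
      16L * v[c(FALSE, FALSE, TRUE, FALSE)] +
      64L * v[c(FALSE, FALSE, FALSE, TRUE)]
    writeBin(as.raw(byte), con)
  }
  invisible(path_prefix)
}
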