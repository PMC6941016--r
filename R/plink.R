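# PLINK 1 binary (bed/bim/fam) reader and writer.
#
# The bed payload is SNP-major, two bits per call, low-order bits first
# within each byte: 00 = homozygous allele1, 10 = heterozygous,
# 11 = homozygous allele2, 01 = missing.  Dosages count allele2, so the
# byte codes map to dosages 0 / 1 / 2 / NA respectively.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosages of the four samples packed into one byte
.bed_decode_lut <- local({
  code2dos <- c(0L, NA_integer_, 1L, 2L) # indexed by 2-bit code + 1
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    lut[b + 1L, ] <- code2dos[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }
  lut
})

#' Read PLINK bed/bim/fam genotypes
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_matrix()] with dosages counting the `allele2` (second
#'   bim allele) copies; heterozygotes are coded 1.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  dup <- bim$snp_id[duplicated(bim$snp_id)]
  if (length(dup)) stop("duplicate SNP ids in bim: ", paste(unique(dup), collapse = ", "))
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC[1:2])) {
    stop("not a PLINK bed file (bad magic number): ", bed_path)
  }
  if (raw[3] != .BED_MAGIC[3]) stop("only SNP-major bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3L + bytes_per_snp * m
  if (length(raw) != expected) {
    stop(sprintf("bed size mismatch: %d bytes, expected %d for %d individuals x %d SNPs",
                 length(raw), expected, n, m))
  }
  payload <- as.integer(raw[-(1:3)])
  # decode 4 samples per byte, then trim padding rows
  dec <- .bed_decode_lut[payload + 1L, , drop = FALSE] # (bytes_per_snp*m) x 4
  dec <- matrix(t(dec), nrow = 4L * bytes_per_snp, ncol = m)
  dosages <- dec[seq_len(n), , drop = FALSE]
  genotype_matrix(
    dosages,
    snp_meta = bim[, c("chrom", "snp_id", "pos", "allele1", "allele2")],
    individual_ids = as.character(fam[[2]])
  )
}

#' Write PLINK bed/bim/fam genotypes
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- n_ind(geno)
  m <- n_snp(geno)
  # dosage -> 2-bit code
  dos2code <- c(0L, 2L, 3L) # dosage 0,1,2
  codes <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m) # pad = missing code 01
  dos <- geno$dosages
  cd <- dos2code[dos + 1L]
  cd[is.na(cd)] <- 1L
  codes[seq_len(n), ] <- cd
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] + 64L * codes[4L, ]
  writeBin(c(.BED_MAGIC, as.raw(bytes)), paste0(prefix, ".bed"))
  bim <- data.frame(
    chrom = geno$snp_meta$chrom, snp_id = geno$snp_meta$snp_id, cm = 0,
    pos = geno$snp_meta$pos, allele1 = geno$snp_meta$allele1,
    allele2 = geno$snp_meta$allele2
  )
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    fid = geno$individual_ids, iid = geno$individual_ids,
    pat = 0, mat = 0, sex = 0, pheno = -9
  )
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write a phenotype/covariate table
#'
#' Tab-delimited with header, columns `id`, `trait`, then covariates.
#'
#' @param phenotypes data frame with at least columns `id` and `trait`.
#' @param path output file.
#' @export
write_pheno <- function(phenotypes, path) {
  stopifnot(all(c("id", "trait") %in% names(phenotypes)))
  write.table(phenotypes, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table written by [write_pheno()]
#'
#' @param path tab-delimited file with header.
#' @return data frame with `year` and `sex` as factors when present.
#' @export
read_pheno <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ph$id <- as.character(ph$id)
  for (v in c("year", "sex")) if (v %in% names(ph)) ph[[v]] <- factor(ph[[v]])
  ph
}
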