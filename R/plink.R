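# PLINK 1 binary (BED/BIM/FAM) reader and writer.
#
# BED layout: magic bytes 0x6C 0x1B, mode byte 0x01 (SNP-major), then for each
# SNP ceiling(n/4) bytes packing 4 genotypes per byte, lowest-order bits first.
# 2-bit codes: 00 hom A1, 01 missing, 10 het, 11 hom A2. Our genotype matrix
# stores the count of the A2 allele, so 0 -> 00, 1 -> 10, 2 -> 11, NA -> 01.

#' Write a genotype dataset as a PLINK BED/BIM/FAM triplet
#'
#' Also writes a `<prefix>.pop` sidecar (`FID IID population`) and, when the
#' dataset carries simulation truth, a `<prefix>.truth.tsv` sidecar with true
#' per-population allele frequencies and (if present) true effects.
#'
#' @param dataset A `genotype_dataset`.
#' @param prefix Path prefix for the output files.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  n <- nrow(G); m <- ncol(G)
  codes <- matrix(3L, n, m)          # 11: hom A2 (genotype 2)
  codes[G == 0L] <- 0L               # 00: hom A1
  codes[G == 1L] <- 2L               # 10: het
  codes[is.na(G)] <- 1L              # 01: missing
  n_pad <- 4L * ceiling(n / 4L)
  if (n_pad > n) codes <- rbind(codes, matrix(0L, n_pad - n, m))
  dim(codes) <- c(4L, n_pad / 4L * m)
  bytes <- as.integer(crossprod(codes, c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)
  st <- dataset$snp_table
  utils::write.table(
    data.frame(st$chr, st$id, 0, st$pos, st$allele1, st$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  sa <- dataset$sample_table
  utils::write.table(
    data.frame(sa$fid, sa$iid, 0, 0, sa$sex, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sa$fid, sa$iid, sa$pop),
    paste0(prefix, ".pop"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- data.frame(snp = st$id, p1 = dataset$truth$p1, p2 = dataset$truth$p2)
    if (!is.null(dataset$truth$beta)) {
      tr$beta1 <- dataset$truth$beta[, 1L]
      tr$beta2 <- dataset$truth$beta[, 2L]
    }
    utils::write.table(tr, paste0(prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM triplet
#'
#' Genotypes are returned as counts of the BIM A2 allele. Malformed magic
#' bytes, truncated payloads and BIM/FAM/BED dimension mismatches are reported
#' as distinct errors. `<prefix>.pop` and `<prefix>.truth.tsv` sidecars written
#' by [write_plink()] are restored when present.
#'
#' @param prefix Path prefix of the triplet.
#' @return A `genotype_dataset`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "allele1", "allele2"),
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop("not a PLINK BED file (bad magic bytes): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major BED files are supported: ", bed_path)
  bps <- ceiling(n / 4L)                  # bytes per SNP
  payload <- length(raw) - 3L
  if (payload < bps * m) {
    stop(sprintf("truncated BED payload: %d bytes, expected %d (n=%d, m=%d)",
                 payload, bps * m, n, m))
  }
  if (payload != bps * m) {
    stop(sprintf("BED payload size (%d bytes) does not match BIM/FAM dimensions (expected %d)",
                 payload, bps * m))
  }
  v <- as.integer(raw[-(1:3)])
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  G <- matrix(NA_integer_, n, m)
  G[codes == 0L] <- 0L
  G[codes == 2L] <- 1L
  G[codes == 3L] <- 2L
  sample_table <- data.frame(fid = as.character(fam$fid), iid = as.character(fam$iid),
                             pop = NA_character_, sex = fam$sex, admix = NA_real_,
                             stringsAsFactors = FALSE)
  pop_path <- paste0(prefix, ".pop")
  if (file.exists(pop_path)) {
    pop <- utils::read.table(pop_path, header = FALSE,
                             col.names = c("fid", "iid", "pop"),
                             stringsAsFactors = FALSE)
    key <- match(paste(sample_table$fid, sample_table$iid), paste(pop$fid, pop$iid))
    sample_table$pop <- pop$pop[key]
  }
  truth <- NULL
  truth_path <- paste0(prefix, ".truth.tsv")
  if (file.exists(truth_path)) {
    tr <- utils::read.table(truth_path, header = TRUE, stringsAsFactors = FALSE)
    truth <- list(p1 = tr$p1, p2 = tr$p2)
    if (!is.null(tr$beta1)) truth$beta <- cbind(tr$beta1, tr$beta2)
  }
  snp_table <- bim[, c("id", "chr", "pos", "allele1", "allele2")]
  new_genotype_dataset(G, snp_table, sample_table, truth)
}
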