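# Genomic relationship matrices, principal components, GCTA binary GRM IO.

#' Standardise genotypes by allele frequency
#'
#' Applies z = (x - 2p) / sqrt(2 p (1 - p)) per SNP, where x is the count of
#' the counted allele and p its frequency. Missing genotypes become 0 after
#' centering (mean imputation on the standardised scale).
#'
#' @param genotypes n x m matrix of 0/1/2 allele counts (`NA` allowed).
#' @param frequencies Length-m vector of counted-allele frequencies in (0, 1).
#' @return n x m numeric matrix.
#' @export
standardize_genotypes <- function(genotypes, frequencies) {
  stopifnot(ncol(genotypes) == length(frequencies))
  if (any(frequencies <= 0 | frequencies >= 1)) {
    stop("allele frequencies must be strictly inside (0, 1)")
  }
  Z <- sweep(genotypes, 2L, 2 * frequencies)
  Z <- sweep(Z, 2L, sqrt(2 * frequencies * (1 - frequencies)), "/")
  Z[is.na(Z)] <- 0
  Z
}

#' Compute a genomic relationship matrix
#'
#' A = Z Z' / m with Z the standardised genotypes. With
#' `mode = "specific"` each individual is standardised by its own population's
#' allele frequencies; with `mode = "average"` pooled frequencies are used.
#' With missing genotypes, entries are divided by the per-pair count of SNPs
#' observed in both individuals instead of m.
#'
#' @param dataset A `genotype_dataset` (with population labels in
#'   `sample_table$pop` when `mode = "specific"`).
#' @param mode `"specific"` or `"average"` frequency standardisation.
#' @param snps Optional SNP subset (indices or logical).
#' @param frequencies Optional externally supplied frequencies: a vector
#'   (`mode = "average"`) or a list with one vector per population
#'   (`mode = "specific"`). Default: estimated from the analysis sample.
#' @return A `grm` object: `matrix`, `sample_ids`, `m_snps`, `mode`.
#' @export
compute_grm <- function(dataset, mode = c("specific", "average"), snps = NULL,
                        frequencies = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "genotype_dataset"))
  ds <- if (is.null(snps)) dataset else subset_snps(dataset, snps)
  G <- ds$genotypes
  if (ncol(G) < 2L) stop("need at least 2 SNPs to build a GRM")
  n <- nrow(G)
  Z <- matrix(0, n, ncol(G))
  if (mode == "specific") {
    pops <- ds$sample_table$pop
    if (anyNA(pops)) stop("mode = \"specific\" requires population labels")
    for (k in unique(pops)) {
      idx <- which(pops == k)
      if (length(idx) < 2L) stop("each population needs at least 2 samples")
      p <- if (!is.null(frequencies)) frequencies[[k]]
           else colMeans(G[idx, , drop = FALSE], na.rm = TRUE) / 2
      if (any(!is.finite(p) | p <= 0 | p >= 1)) {
        stop(sprintf("monomorphic SNP within population %s", k))
      }
      Z[idx, ] <- standardize_genotypes(G[idx, , drop = FALSE], p)
    }
  } else {
    p <- if (!is.null(frequencies)) frequencies
         else colMeans(G, na.rm = TRUE) / 2
    if (any(!is.finite(p) | p <= 0 | p >= 1)) stop("monomorphic SNP in combined sample")
    Z <- standardize_genotypes(G, p)
  }
  if (anyNA(G)) {
    obs <- !is.na(G)
    storage.mode(obs) <- "double"
    N <- tcrossprod(obs)
    A <- tcrossprod(Z) / N
    m_snps <- N
  } else {
    A <- tcrossprod(Z) / ncol(G)
    m_snps <- ncol(G)
  }
  structure(list(matrix = A,
                 sample_ids = ds$sample_table[, c("fid", "iid")],
                 m_snps = m_snps, mode = mode,
                 pop = ds$sample_table$pop),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %s SNPs, mode = %s\n", nrow(x$matrix),
              if (is.matrix(x$m_snps)) "pairwise" else x$m_snps, x$mode))
  invisible(x)
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors scaled by the square root of their eigenvalues, in
#' descending eigenvalue order. Each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param grm A `grm` object or symmetric matrix.
#' @param k Number of components.
#' @return n x k matrix with attribute `eigenvalues`.
#' @export
compute_pcs <- function(grm, k = 20L) {
  A <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  if (!all(is.finite(A))) stop("GRM contains non-finite entries")
  n <- nrow(A)
  stopifnot(k >= 1L, k <= n)
  ev <- eigen(A, symmetric = TRUE)
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  val <- ev$values[seq_len(k)]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(vec[, j]))
    if (vec[i0, j] < 0) vec[, j] <- -vec[, j]
  }
  pcs <- sweep(vec, 2L, sqrt(pmax(val, 0)), "*")
  colnames(pcs) <- sprintf("PC%d", seq_len(k))
  attr(pcs, "eigenvalues") <- val
  attr(pcs, "vectors") <- vec
  pcs
}

#' Write / read a GCTA binary GRM triplet
#'
#' `<prefix>.grm.bin` holds the lower triangle (including the diagonal) in
#' row-major order as 4-byte little-endian floats; `<prefix>.grm.N.bin` the
#' matching per-pair SNP counts; `<prefix>.grm.id` the `FID IID` lines.
#'
#' @param grm A `grm` object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$matrix
  ut <- upper.tri(A, diag = TRUE)       # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A[ut]), con, size = 4L, endian = "little")
  close(con)
  Nv <- if (is.matrix(grm$m_snps)) grm$m_snps[ut] else rep(grm$m_snps, sum(ut))
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(Nv), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$sample_ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @return `read_gcta_grm()` returns a `grm` object (float32 precision).
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           col.names = c("fid", "iid"), stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_tri <- n * (n + 1) / 2
  path <- paste0(prefix, ".grm.bin")
  v <- readBin(path, "numeric", n = file.info(path)$size / 4, size = 4L,
               endian = "little")
  if (length(v) != n_tri) {
    stop(sprintf("GRM size mismatch: %d values in .grm.bin but %d ids imply %d",
                 length(v), n, n_tri))
  }
  A <- matrix(0, n, n)
  ut <- upper.tri(A, diag = TRUE)
  A[ut] <- v
  A <- A + t(A) - diag(diag(A))
  npath <- paste0(prefix, ".grm.N.bin")
  m_snps <- NULL
  if (file.exists(npath)) {
    nv <- readBin(npath, "numeric", n = file.info(npath)$size / 4, size = 4L,
                  endian = "little")
    if (length(nv) == n_tri) {
      if (length(unique(nv)) == 1L) {
        m_snps <- nv[1]
      } else {
        N <- matrix(0, n, n); N[ut] <- nv
        m_snps <- N + t(N) - diag(diag(N))
      }
    }
  }
  structure(list(matrix = A, sample_ids = ids, m_snps = m_snps,
                 mode = "unknown", pop = NULL), class = "grm")
}
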