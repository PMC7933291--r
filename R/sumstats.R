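# Per-SNP association scan, LD clumping to sentinel SNPs, split-sample
# re-estimation, and the error-corrected cross-population SNP-effect
# correlation r_b with its jackknife standard error.

#' Per-SNP association scan
#'
#' Covariate-adjusted least squares: the phenotype and each genotype are
#' residualised on the covariates (plus an intercept), and the per-allele
#' effect, standard error and P-value are computed per SNP. The effect allele
#' (A1 of the output) is the counted allele (BIM A2). Monomorphic SNPs are
#' skipped with a message.
#'
#' @param dataset A `genotype_dataset`.
#' @param phenotype Numeric phenotype vector aligned with the samples (`NA`
#'   dropped).
#' @param covariates Optional covariate matrix.
#' @param snps Optional SNP subset to scan.
#' @return A `sumstats` data.frame: `SNP, A1, A2, freq, b, se, p, N` (COJO .ma
#'   layout).
#' @export
gwas_scan <- function(dataset, phenotype, covariates = NULL, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            length(phenotype) == nrow(dataset$genotypes))
  ds <- if (is.null(snps)) dataset else subset_snps(dataset, snps)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  G <- ds$genotypes[keep, , drop = FALSE]
  X <- matrix(1, length(y), 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[keep, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariates are not full rank")
  n <- length(y)
  storage.mode(G) <- "double"
  if (anyNA(G)) {                       # mean-impute for residualisation
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2L]]
  }
  freq <- colMeans(G) / 2
  yr <- qr.resid(qx, y)
  Gr <- qr.resid(qx, G)
  xx <- colSums(Gr^2)
  mono <- xx <= n * 1e-12
  if (any(mono)) {
    message(sprintf("%d monomorphic SNP(s) skipped in the scan", sum(mono)))
  }
  xy <- as.numeric(crossprod(Gr, yr))
  b <- xy / xx
  df <- n - ncol(X) - 1L
  rss <- pmax(sum(yr^2) - b * xy, 0)
  se <- sqrt(rss / (df * xx))
  tt <- b / se
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  out <- data.frame(SNP = ds$snp_table$id,
                    A1 = ds$snp_table$allele2,     # counted (effect) allele
                    A2 = ds$snp_table$allele1,
                    freq = freq, b = b, se = se, p = p, N = n,
                    stringsAsFactors = FALSE)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Read / write COJO-style .ma summary statistics
#'
#' Whitespace-delimited with header `SNP A1 A2 freq b se p N`.
#'
#' @param sumstats A `sumstats` data.frame.
#' @param path Output file path.
#' @return `write_ma()` returns the path invisibly; `read_ma()` a `sumstats`
#'   data.frame.
#' @export
write_ma <- function(sumstats, path) {
  utils::write.table(sumstats[, c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")],
                     path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ma
#' @export
read_ma <- function(path) {
  out <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  if (!all(need %in% names(out))) {
    stop("missing .ma columns: ", paste(setdiff(need, names(out)), collapse = ", "))
  }
  if (any(out$se <= 0)) stop("se must be positive")
  if (any(out$A1 == out$A2)) stop("effect and other allele must differ")
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Greedy LD clumping to sentinel SNPs
#'
#' Repeatedly takes the smallest-P SNP below `p_threshold` not yet assigned to
#' a clump, makes it a sentinel, and assigns to its clump every unassigned SNP
#' within `window_kb` whose LD r-squared with the sentinel exceeds
#' `r2_threshold`. Ties in P are broken by position, then id.
#'
#' @param sumstats A `sumstats` data.frame.
#' @param dataset A `genotype_dataset` supplying the LD reference (must
#'   contain the scanned SNPs).
#' @param p_threshold Significance threshold (default 5e-8).
#' @param r2_threshold LD threshold (default 0.01).
#' @param window_kb Window half-width in kb (default 1000).
#' @return A `sentinel_set`: list with `sentinels` (ids in selection order)
#'   and `clumps` (data.frame snp, clump).
#' @export
clump <- function(sumstats, dataset, p_threshold = 5e-8, r2_threshold = 0.01,
                  window_kb = 1000) {
  st <- dataset$snp_table
  pos_of <- match(sumstats$SNP, st$id)
  if (anyNA(pos_of)) stop("sumstats SNPs missing from the LD reference")
  pos <- st$pos[pos_of]; chr <- st$chr[pos_of]
  G <- dataset$genotypes[, pos_of, drop = FALSE]
  storage.mode(G) <- "double"
  m <- nrow(sumstats)
  assigned <- rep(NA_character_, m)
  cand <- order(sumstats$p, pos, sumstats$SNP)
  cand <- cand[sumstats$p[cand] < p_threshold]
  sentinels <- character(0)
  for (i in cand) {
    if (!is.na(assigned[i])) next
    sid <- sumstats$SNP[i]
    sentinels <- c(sentinels, sid)
    assigned[i] <- sid
    near <- which(is.na(assigned) & chr == chr[i] &
                  abs(pos - pos[i]) <= window_kb * 1000)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(G[, i], G[, near, drop = FALSE]))
      hit <- near[!is.na(r) & r^2 > r2_threshold]
      assigned[hit] <- sid
    }
  }
  structure(list(sentinels = sentinels,
                 clumps = data.frame(snp = sumstats$SNP, clump = assigned,
                                     stringsAsFactors = FALSE)),
            class = "sentinel_set")
}

#' Two-round clumping with an enlarged second window
#'
#' Round 1 clumps at `window_kb`; round 2 re-clumps the round-1 sentinels with
#' a much larger window (`window2_kb`) to remove residual long-range LD
#' between sentinels.
#'
#' @inheritParams clump
#' @param window2_kb Second-round window half-width in kb (default 10000).
#' @return A `sentinel_set` (the round-2 result), with the round-1 result in
#'   `$round1`.
#' @export
clump_two_round <- function(sumstats, dataset, p_threshold = 5e-8,
                            r2_threshold = 0.01, window_kb = 1000,
                            window2_kb = 10000) {
  r1 <- clump(sumstats, dataset, p_threshold, r2_threshold, window_kb)
  ss1 <- sumstats[sumstats$SNP %in% r1$sentinels, , drop = FALSE]
  r2 <- clump(ss1, dataset, p_threshold, r2_threshold, window2_kb)
  r2$round1 <- r1
  r2
}

#' Split-sample re-estimation of sentinel effects
#'
#' Splits the samples disjointly into a discovery and an estimation set and
#' re-estimates the effects at the sentinel SNPs in each, emulating the
#' discovery-cohort / independent-re-estimation design that avoids winner's
#' curse.
#'
#' @param dataset A `genotype_dataset`.
#' @param phenotype Phenotype vector.
#' @param sentinel_ids Sentinel SNP ids.
#' @param covariates Optional covariates.
#' @param discovery_fraction Fraction of samples in the discovery half.
#' @param seed Integer seed for the split.
#' @return List with `discovery` and `estimation` `sumstats` (at the
#'   sentinels) and the index vectors `discovery_idx`, `estimation_idx`.
#' @export
split_sample_reestimate <- function(dataset, phenotype, sentinel_ids,
                                    covariates = NULL,
                                    discovery_fraction = 0.5, seed = 1L) {
  stopifnot(length(sentinel_ids) >= 1,
            discovery_fraction > 0, discovery_fraction < 1)
  n <- nrow(dataset$genotypes)
  idx_d <- with_seed(seed, sort(sample.int(n, round(n * discovery_fraction))))
  idx_e <- setdiff(seq_len(n), idx_d)
  if (length(intersect(idx_d, idx_e))) stop("sample splits overlap")
  snps <- match(sentinel_ids, dataset$snp_table$id)
  if (anyNA(snps)) stop("sentinel ids missing from the dataset")
  snps <- sort(snps)
  cov_d <- if (is.null(covariates)) NULL else as.matrix(covariates)[idx_d, , drop = FALSE]
  cov_e <- if (is.null(covariates)) NULL else as.matrix(covariates)[idx_e, , drop = FALSE]
  list(discovery = gwas_scan(subset_samples(dataset, idx_d), phenotype[idx_d],
                             cov_d, snps = snps),
       estimation = gwas_scan(subset_samples(dataset, idx_e), phenotype[idx_e],
                              cov_e, snps = snps),
       discovery_idx = idx_d, estimation_idx = idx_e)
}

# Align two sumstats tables on shared SNPs with a common effect allele;
# effects whose alleles are swapped have their sign (and frequency) flipped.
harmonize_sumstats <- function(ss_a, ss_b, ids = NULL) {
  if (is.null(ids)) ids <- intersect(ss_a$SNP, ss_b$SNP)
  a <- ss_a[match(ids, ss_a$SNP), , drop = FALSE]
  b <- ss_b[match(ids, ss_b$SNP), , drop = FALSE]
  ok <- !is.na(a$SNP) & !is.na(b$SNP)
  a <- a[ok, ]; b <- b[ok, ]
  same <- a$A1 == b$A1 & a$A2 == b$A2
  flip <- a$A1 == b$A2 & a$A2 == b$A1
  drop <- !(same | flip)
  if (any(drop)) {
    warning(sprintf("%d SNP(s) dropped: alleles cannot be matched", sum(drop)),
            call. = FALSE)
  }
  a <- a[!drop, ]; b <- b[!drop, ]
  flip <- flip[!drop]
  b$b[flip] <- -b$b[flip]
  b$freq[flip] <- 1 - b$freq[flip]
  b$A1[flip] <- a$A1[flip]; b$A2[flip] <- a$A2[flip]
  list(a = a, b = b)
}

rb_point <- function(ba, bb, se2a, se2b) {
  va <- stats::var(ba) - mean(se2a)
  vb <- stats::var(bb) - mean(se2b)
  if (va <= 0 || vb <= 0) return(NA_real_)
  stats::cov(ba, bb) / sqrt(va * vb)
}

#' Error-corrected correlation of SNP effects between two GWAS
#'
#' Moment-based errors-in-variables estimator at a set of sentinel SNPs:
#' \deqn{r_b = \frac{cov(\hat b_a, \hat b_b)}
#'   {\sqrt{(var(\hat b_a) - \overline{se_a^2})(var(\hat b_b) - \overline{se_b^2})}}}
#' which removes the attenuation caused by estimation error in both sets of
#' effects (assumed independent between the two GWAS). The standard error is
#' computed by delete-one jackknife over sentinels.
#'
#' @param sumstats_a,sumstats_b Two independent `sumstats` tables.
#' @param sentinel_ids Optional sentinel subset (default: all shared SNPs).
#' @return List with `rb`, `se`, `k` (sentinels used), `r_naive` (uncorrected
#'   Pearson correlation) and the aligned effect table `data`. `rb` is `NA`
#'   with a warning when the error-corrected variance is non-positive (noise
#'   exceeds signal).
#' @export
rb_estimate <- function(sumstats_a, sumstats_b, sentinel_ids = NULL) {
  h <- harmonize_sumstats(sumstats_a, sumstats_b, sentinel_ids)
  k <- nrow(h$a)
  if (k < 10L) stop("need at least 10 matched sentinel SNPs")
  if (identical(h$a$b, h$b$b) && identical(h$a$se, h$b$se)) {
    stop("the two summary-statistics sets are identical; r_b requires independent errors")
  }
  ba <- h$a$b; bb <- h$b$b
  se2a <- h$a$se^2; se2b <- h$b$se^2
  rb <- rb_point(ba, bb, se2a, se2b)
  if (is.na(rb)) {
    warning("error-corrected variance is non-positive: r_b undefined (noise exceeds signal)",
            call. = FALSE)
    return(list(rb = NA_real_, se = NA_real_, k = k,
                r_naive = stats::cor(ba, bb),
                data = data.frame(SNP = h$a$SNP, b_a = ba, se_a = h$a$se,
                                  b_b = bb, se_b = h$b$se)))
  }
  loo <- vapply(seq_len(k), function(j) {
    rb_point(ba[-j], bb[-j], se2a[-j], se2b[-j])
  }, numeric(1))
  loo_ok <- loo[is.finite(loo)]
  se <- sqrt((length(loo_ok) - 1) / length(loo_ok) *
             sum((loo_ok - mean(loo_ok))^2))
  list(rb = rb, se = se, k = k, r_naive = stats::cor(ba, bb),
       data = data.frame(SNP = h$a$SNP, b_a = ba, se_a = h$a$se,
                         b_b = bb, se_b = h$b$se))
}

#' Same-population negative control for r_b
#'
#' Splits one population's samples into two disjoint halves, scans both at the
#' sentinel SNPs, and estimates r_b between the halves. Since both halves
#' share the same underlying effects, the expectation is r_b of about 1.
#'
#' @param dataset A single-population `genotype_dataset` (or any dataset; the
#'   split is over all its samples).
#' @param phenotype Phenotype vector.
#' @param sentinel_ids Sentinel SNP ids.
#' @param covariates Optional covariates.
#' @param seed Seed for the split.
#' @return As [rb_estimate()].
#' @export
negative_control <- function(dataset, phenotype, sentinel_ids,
                             covariates = NULL, seed = 1L) {
  sp <- split_sample_reestimate(dataset, phenotype, sentinel_ids,
                                covariates = covariates,
                                discovery_fraction = 0.5, seed = seed)
  rb_estimate(sp$discovery, sp$estimation)
}
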