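# Per-SNP FST, per-population LD scores, LDCV, MAF/LD-matched binning and the
# low/high split used for two-component stratified GREML.

#' Per-SNP FST between two populations
#'
#' Default estimator is Hudson's:
#' \deqn{F = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                {p_1(1-p_2) + p_2(1-p_1)}}
#' where n is the number of sampled allele copies (2x diploid individuals);
#' the finite-sample correction then makes the numerator unbiased for the
#' squared frequency divergence. The Weir-Cockerham two-population estimator
#' (expected heterozygosity under HWE) is available via `estimator = "wc"`.
#' Negative estimates are retained, not clipped. SNPs with a zero denominator
#' (both frequencies 0 or both 1) get `NA` with a message.
#'
#' @param p1,p2 Counted-allele frequencies per population.
#' @param n1,n2 Number of sampled allele copies per population (>= 2).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return Numeric vector of per-SNP FST estimates.
#' @export
fst_per_snp <- function(p1, n1, p2, n2, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1), n1 >= 2, n2 >= 2)
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir & Cockerham (1984) for r = 2 populations, heterozygosity taken at
    # its HWE expectation 2p(1-p)
    ni <- c(n1, n2) / 2                     # diploid sample sizes
    r <- 2
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- (ni[1] * p1 + ni[2] * p2) / sum(ni)
    s2 <- (ni[1] * (p1 - pbar)^2 + ni[2] * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (ni[1] * 2 * p1 * (1 - p1) + ni[2] * 2 * p2 * (1 - p2)) / sum(ni)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
  }
  bad <- den == 0
  if (any(bad)) {
    message(sprintf("%d SNP(s) with undefined FST (zero denominator) set to NA",
                    sum(bad)))
  }
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Genome-wide mean FST as a ratio of averages
#'
#' Averages the Hudson estimator across SNPs as the ratio of the summed
#' numerators to the summed denominators. Unlike the arithmetic mean of the
#' per-SNP ratios -- which is biased for the divergence parameter because the
#' per-SNP denominators vary -- the ratio of averages is consistent for it,
#' and is the standard way to combine Hudson FST across loci.
#'
#' @inheritParams fst_per_snp
#' @return A single genome-wide FST estimate.
#' @export
fst_mean <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

#' Per-SNP LD scores within one population
#'
#' For SNP j, the LD score is the sum over all SNPs k on the same chromosome
#' within `window_kb` of the bias-adjusted squared correlation
#' r2 - (1 - r2)/(n - 2), including the SNP itself (self contribution 1).
#'
#' @param genotypes n x m genotype matrix for one population.
#' @param positions Base-pair positions (sorted within chromosome).
#' @param chr Optional chromosome labels (default: single chromosome).
#' @param window_kb Window half-width in kb (default 1000).
#' @param adjust Apply the finite-sample bias adjustment (default TRUE).
#' @return Numeric vector of per-SNP LD scores (`NA` for monomorphic SNPs).
#' @export
ld_scores <- function(genotypes, positions, chr = NULL, window_kb = 1000,
                      adjust = TRUE) {
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  if (n <= 2L) stop("LD scores need more than 2 samples")
  stopifnot(length(positions) == m, window_kb >= 0)
  if (is.null(chr)) chr <- rep(1L, m)
  out <- rep(NA_real_, m)
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    pos <- positions[idx]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
    X <- genotypes[, idx, drop = FALSE]
    sds <- apply(X, 2L, stats::sd)
    poly <- sds > 0
    Z <- matrix(0, n, length(idx))
    Z[, poly] <- scale(X[, poly, drop = FALSE])
    w <- window_kb * 1000
    lo <- findInterval(pos - w, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + w, pos)
    ell <- rep(NA_real_, length(idx))
    chunk <- 512L
    for (s in seq(1L, length(idx), by = chunk)) {
      e <- min(s + chunk - 1L, length(idx))
      rng <- min(lo[s:e]):max(hi[s:e])
      R <- crossprod(Z[, s:e, drop = FALSE], Z[, rng, drop = FALSE]) / (n - 1)
      r2 <- R^2
      if (adjust) r2 <- r2 - (1 - r2) / (n - 2)
      for (j in s:e) {
        if (!poly[j]) next
        cols <- (lo[j]:hi[j]) - rng[1L] + 1L
        keep <- poly[lo[j]:hi[j]]
        ell[j] <- sum(r2[j - s + 1L, cols[keep]])
      }
    }
    out[idx] <- ell
  }
  out
}

#' LD-score coefficient of variation across two populations
#'
#' CV = sample standard deviation of the two scores divided by their mean,
#' i.e. |l1 - l2| / (sqrt(2) * mean(l1, l2)).
#'
#' @param ld_score_pop1,ld_score_pop2 Per-SNP LD scores (>= 0).
#' @return Per-SNP LDCV.
#' @export
ldcv <- function(ld_score_pop1, ld_score_pop2) {
  stopifnot(length(ld_score_pop1) == length(ld_score_pop2))
  mu <- (ld_score_pop1 + ld_score_pop2) / 2
  if (any(mu <= 0, na.rm = TRUE)) stop("mean LD score must be positive")
  abs(ld_score_pop1 - ld_score_pop2) / (sqrt(2) * mu)
}

#' MAF/LD-matched joint bins
#'
#' SNPs are first split into `n_freq_bins` equal-count bins on the
#' population-1 MAF and `n_freq_bins` bins on the frequency of the same
#' counted allele in population 2 (crossed). Within each joint frequency bin,
#' SNPs are further split into `n_ld_bins` equal-count bins on each
#' population's LD score (crossed), nested inside the frequency bin. The
#' number of possible joint bins is `n_freq_bins^2 * n_ld_bins^2`.
#'
#' @param p1,p2 Counted-allele frequencies per population (population-1 MAF is
#'   derived internally).
#' @param ld1,ld2 Per-SNP LD scores per population.
#' @param n_freq_bins Frequency bins per axis (e.g. 125, or 20 for the LDCV
#'   configuration).
#' @param n_ld_bins LD bins per axis (e.g. 4, or 25 for the LDCV
#'   configuration).
#' @return Integer vector of joint bin indices with attributes
#'   `n_bins_possible` and `axes` (a data.frame of the four axis indices).
#' @export
make_bins <- function(p1, p2, ld1, ld2, n_freq_bins, n_ld_bins) {
  m <- length(p1)
  stopifnot(length(p2) == m, length(ld1) == m, length(ld2) == m,
            n_freq_bins >= 1, n_ld_bins >= 1)
  maf1 <- pmin(p1, 1 - p1)
  fb1 <- quantile_bins(maf1, n_freq_bins, warn = FALSE)
  fb2 <- quantile_bins(p2, n_freq_bins, warn = FALSE)
  freq_bin <- (fb1 - 1L) * n_freq_bins + fb2
  lb1 <- integer(m); lb2 <- integer(m)
  for (idx in split(seq_len(m), freq_bin)) {
    lb1[idx] <- quantile_bins(ld1[idx], n_ld_bins, warn = FALSE)
    lb2[idx] <- quantile_bins(ld2[idx], n_ld_bins, warn = FALSE)
  }
  bin <- ((freq_bin - 1L) * n_ld_bins + (lb1 - 1L)) * n_ld_bins + lb2
  attr(bin, "n_bins_possible") <- as.numeric(n_freq_bins)^2 * as.numeric(n_ld_bins)^2
  attr(bin, "axes") <- data.frame(freq_bin_1 = fb1, freq_bin_2 = fb2,
                                  ld_bin_1 = lb1, ld_bin_2 = lb2)
  bin
}

#' Split SNPs into low/high groups within matched bins
#'
#' Within each bin, SNPs are sorted by the stratification metric (ties broken
#' by SNP index); the lower half goes to the `low` group and the upper half to
#' `high`. In odd-sized bins the median SNP is assigned to either group by a
#' seeded coin flip, so group sizes are equal to within one per bin.
#'
#' @param bins Bin index per SNP (from [make_bins()]).
#' @param metric Stratification metric per SNP (e.g. FST or LDCV); must be
#'   finite.
#' @param seed Integer seed for the odd-bin randomisation.
#' @return Factor with levels `low`, `high`, aligned with the input order.
#' @export
split_within_bins <- function(bins, metric, seed = 1L) {
  m <- length(bins)
  stopifnot(length(metric) == m, all(is.finite(metric)))
  ord <- order(bins, metric, seq_len(m))
  sizes <- rle(bins[ord])$lengths
  pos_in_bin <- sequence(sizes)
  size_rep <- rep(sizes, sizes)
  group <- rep(NA_character_, m)
  low_cut <- floor(size_rep / 2)
  is_low <- pos_in_bin <= low_cut
  is_high <- pos_in_bin > size_rep - low_cut
  is_mid <- !is_low & !is_high                 # only present in odd bins
  group[ord[is_low]] <- "low"
  group[ord[is_high]] <- "high"
  n_mid <- sum(is_mid)
  if (n_mid > 0) {
    flips <- with_seed(seed, stats::runif(n_mid) < 0.5)
    group[ord[is_mid]] <- ifelse(flips, "high", "low")
  }
  factor(group, levels = c("low", "high"))
}

#' Full per-SNP stratification table
#'
#' Computes per-SNP FST, LD scores per population, LDCV, joint bin and
#' low/high group for a two-population dataset, using sample allele
#' frequencies.
#'
#' @param dataset A `genotype_dataset` with population labels.
#' @param metric `"fst"` or `"ldcv"`: the stratification metric.
#' @param n_freq_bins,n_ld_bins Binning resolution (defaults: 125 and 4 for
#'   FST; use 20 and 25 for LDCV).
#' @param window_kb LD-score window (default 1000).
#' @param seed Seed for the odd-bin randomisation.
#' @return Data frame: snp, freq1, freq2, fst, ld1, ld2, ldcv, bin, group;
#'   attribute `n_bins_possible`.
#' @export
snp_strata <- function(dataset, metric = c("fst", "ldcv"),
                       n_freq_bins = NULL, n_ld_bins = NULL,
                       window_kb = 1000, seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(n_freq_bins)) n_freq_bins <- if (metric == "fst") 125L else 20L
  if (is.null(n_ld_bins)) n_ld_bins <- if (metric == "fst") 4L else 25L
  stopifnot(inherits(dataset, "genotype_dataset"))
  pops <- dataset$sample_table$pop
  i1 <- which(pops == "pop1"); i2 <- which(pops == "pop2")
  stopifnot(length(i1) >= 2, length(i2) >= 2)
  G <- dataset$genotypes
  p1 <- colMeans(G[i1, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(G[i2, , drop = FALSE], na.rm = TRUE) / 2
  fst <- fst_per_snp(p1, 2 * length(i1), p2, 2 * length(i2))
  ld1 <- ld_scores(G[i1, , drop = FALSE], dataset$snp_table$pos,
                   dataset$snp_table$chr, window_kb)
  ld2 <- ld_scores(G[i2, , drop = FALSE], dataset$snp_table$pos,
                   dataset$snp_table$chr, window_kb)
  cv <- ldcv(ld1, ld2)
  met <- if (metric == "fst") fst else cv
  usable <- is.finite(met) & is.finite(ld1) & is.finite(ld2)
  if (!all(usable)) {
    message(sprintf("%d SNP(s) excluded from stratification (undefined metric)",
                    sum(!usable)))
  }
  bin <- rep(NA_integer_, ncol(G))
  group <- factor(rep(NA_character_, ncol(G)), levels = c("low", "high"))
  bin_u <- make_bins(p1[usable], p2[usable], ld1[usable], ld2[usable],
                     n_freq_bins, n_ld_bins)
  group[usable] <- split_within_bins(bin_u, met[usable], seed = seed)
  bin[usable] <- bin_u
  out <- data.frame(snp = dataset$snp_table$id, freq1 = p1, freq2 = p2,
                    fst = fst, ld1 = ld1, ld2 = ld2, ldcv = cv,
                    bin = bin, group = group, stringsAsFactors = FALSE)
  attr(out, "n_bins_possible") <- attr(bin_u, "n_bins_possible")
  out
}

#' Two-component stratified bivariate GREML
#'
#' Builds a population-specific GRM for each SNP group (low and high) and fits
#' both jointly in a bivariate GREML, giving per-group genetic correlations
#' and heritabilities plus the joint sampling covariance needed by
#' [rg_diff_test()].
#'
#' @param dataset A `genotype_dataset` with population labels.
#' @param groups Factor `low`/`high` per SNP (e.g. from [snp_strata()]); `NA`
#'   SNPs are excluded.
#' @param phenotype Numeric phenotype aligned with the samples.
#' @param covariates Optional covariate matrix.
#' @param ... Passed to [bivariate_greml()].
#' @return List with `fit` (a `greml_fit`; component 1 = low, 2 = high) and
#'   `moments` (a `component_moments`).
#' @export
two_component_fit <- function(dataset, groups, phenotype, covariates = NULL, ...) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            length(groups) == ncol(dataset$genotypes))
  idx_low <- which(groups == "low"); idx_high <- which(groups == "high")
  if (!length(idx_low) || !length(idx_high)) stop("both groups must be non-empty")
  g_low <- compute_grm(dataset, mode = "specific", snps = idx_low)
  g_high <- compute_grm(dataset, mode = "specific", snps = idx_high)
  fit <- bivariate_greml(phenotype, dataset$sample_table$pop,
                         list(low = g_low, high = g_high),
                         covariates = covariates, ...)
  list(fit = fit, moments = as_component_moments(fit))
}
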