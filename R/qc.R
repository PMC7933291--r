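# Sample, variant, ancestry-outlier, relatedness and phenotype QC.

#' QC thresholds
#'
#' Container for the filtering thresholds used throughout QC. Defaults follow
#' common practice for array/imputed GWAS data: SNPs are dropped when the
#' missing genotype rate exceeds 0.05 (call rate < 0.95), MAF < 0.01 or the
#' Hardy-Weinberg exact test P < 0.001; samples are dropped when their call
#' rate is below 0.9; principal-component outliers beyond 6 s.d.; one of each
#' pair with genomic relatedness > 0.05; phenotype outliers beyond `pheno_sd_cut`
#' s.d. within sex group.
#'
#' @param snp_missing_max Maximum per-SNP missing genotype rate.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test P-value.
#' @param sample_callrate_min Minimum per-sample call rate (strict `<` removal).
#' @param pc_sd_cut PC1/PC2 outlier multiplier.
#' @param relatedness_max Maximum allowed GRM off-diagonal.
#' @param pheno_sd_cut Phenotype outlier multiplier.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_missing_max = 0.05, maf_min = 0.01,
                          hwe_p_min = 0.001, sample_callrate_min = 0.9,
                          pc_sd_cut = 6, relatedness_max = 0.05,
                          pheno_sd_cut = 7) {
  stopifnot(snp_missing_max >= 0, snp_missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            sample_callrate_min >= 0, sample_callrate_min <= 1,
            pc_sd_cut > 0, relatedness_max > 0, pheno_sd_cut > 0)
  structure(list(snp_missing_max = snp_missing_max, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, sample_callrate_min = sample_callrate_min,
                 pc_sd_cut = pc_sd_cut, relatedness_max = relatedness_max,
                 pheno_sd_cut = pheno_sd_cut), class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact test on observed genotype counts, computed by enumerating all
#' heterozygote counts compatible with the observed allele counts via the
#' standard probability recurrence. The P-value is the total probability of
#' configurations no more probable than the observed one (no mid-p
#' adjustment).
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Observed homozygote counts.
#' @return The exact P-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het   # copies of the rarer allele
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  if (length(hets) == 1L) return(1)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  # going down in het count: P(h-2) = P(h) * h(h-1) / (4 (r+1)(c+1))
  if (mid_i > 1L) {
    for (i in (mid_i - 1L):1L) {
      h <- hets[i + 1L]
      r <- (n_rare - h) / 2; c <- n - h - r
      probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * (r + 1) * (c + 1))
    }
  }
  # going up: P(h+2) = P(h) * 4 r c / ((h+2)(h+1))
  if (mid_i < length(hets)) {
    for (i in (mid_i + 1L):length(hets)) {
      h <- hets[i - 1L]
      r <- (n_rare - h) / 2; c <- n - h - r
      probs[i] <- probs[i - 1L] * 4 * r * c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP quality control
#'
#' Filters SNPs in a fixed order: missingness, then MAF, then Hardy-Weinberg,
#' each criterion applied to the survivors of the previous one. MAF and HWE use
#' non-missing genotypes only.
#'
#' @param dataset A `genotype_dataset`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `dataset` (filtered) and `removed`, a list of SNP ids
#'   removed per criterion (`missingness`, `maf`, `hwe`).
#' @export
snp_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"), ncol(dataset$genotypes) > 0)
  G <- dataset$genotypes
  ids <- dataset$snp_table$id
  miss <- colMeans(is.na(G))
  rm_miss <- miss > thresholds$snp_missing_max
  keep <- !rm_miss
  f <- colMeans(G[, keep, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  rm_maf_local <- is.na(maf) | maf < thresholds$maf_min
  rm_maf <- ids[keep][rm_maf_local]
  keep[keep] <- !rm_maf_local
  hwe_p <- apply(G[, keep, drop = FALSE], 2L, function(x) {
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 1L), sum(x == 0L), sum(x == 2L))
  })
  rm_hwe_local <- hwe_p < thresholds$hwe_p_min
  rm_hwe <- ids[keep][rm_hwe_local]
  keep[keep] <- !rm_hwe_local
  if (!any(keep)) stop("SNP QC removed all SNPs")
  list(dataset = subset_snps(dataset, which(keep)),
       removed = list(missingness = ids[rm_miss], maf = rm_maf, hwe = rm_hwe))
}

#' Per-sample quality control
#'
#' Removes individuals whose genotype call rate falls strictly below
#' `sample_callrate_min`; sample order is otherwise preserved.
#'
#' @inheritParams snp_qc
#' @return List with `dataset` and `removed` (sample iids).
#' @export
sample_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  cr <- 1 - rowMeans(is.na(dataset$genotypes))
  keep <- !(cr < thresholds$sample_callrate_min)
  if (!any(keep)) stop("sample QC removed all samples")
  list(dataset = subset_samples(dataset, which(keep)),
       removed = dataset$sample_table$iid[!keep])
}

#' Ancestry-outlier filter on principal components
#'
#' Removes samples whose PC1 or PC2 lies more than `sd_cut` reference standard
#' deviations from the reference mean. With no external reference the sample's
#' own mean and s.d. are used.
#'
#' @param pcs Numeric matrix with at least two columns (PC1, PC2).
#' @param reference_mean,reference_sd Length-2 reference location/scale;
#'   defaults to the mean/sd of `pcs[, 1:2]`.
#' @param sd_cut Outlier multiplier (default 6).
#' @return Logical vector: `TRUE` for retained samples.
#' @export
pc_outlier_filter <- function(pcs, reference_mean = NULL, reference_sd = NULL,
                              sd_cut = 6) {
  pcs <- as.matrix(pcs)
  stopifnot(ncol(pcs) >= 2L)
  p2 <- pcs[, 1:2, drop = FALSE]
  if (is.null(reference_mean)) reference_mean <- colMeans(p2)
  if (is.null(reference_sd)) reference_sd <- apply(p2, 2L, stats::sd)
  if (any(reference_sd <= 0)) stop("zero reference standard deviation")
  d <- sweep(sweep(p2, 2L, reference_mean[1:2]), 2L, reference_sd[1:2], "/")
  rowSums(abs(d) > sd_cut) == 0L
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops the individual participating in the most GRM off-diagonal
#' pairs above `threshold` (ties broken by lowest sample index) until no pair
#' exceeds the threshold. Deterministic.
#'
#' @param grm A `grm` object or a symmetric relatedness matrix.
#' @param threshold Maximum allowed off-diagonal relatedness (default 0.05).
#' @return Integer indices of retained samples.
#' @export
relatedness_prune <- function(grm, threshold = 0.05) {
  A <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  stopifnot(nrow(A) == ncol(A))
  adj <- A > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    drop_i <- which.max(deg)          # ties -> lowest index
    alive[drop_i] <- FALSE
    adj[drop_i, ] <- FALSE
    adj[, drop_i] <- FALSE
  }
  which(alive)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles via `qnorm((rank - 0.5) / k)` with average
#' ranks for ties; `NA`s are preserved.
#'
#' @param x Numeric vector.
#' @return Transformed vector, mean approximately 0 and variance approximately 1.
#' @export
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  k <- sum(ok)
  if (k > 0) out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / k)
  out
}

#' Prepare a phenotype for variance-component analysis
#'
#' Within each group (e.g. sex within cohort): values more than `sd_cut`
#' standard deviations from the group mean are removed, covariates are
#' regressed out of the survivors, and the residuals are rank-based
#' inverse-normal transformed. Removed and missing entries are returned as
#' `NA`.
#'
#' @param phenotype Numeric vector.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param group Optional grouping vector (default: one group).
#' @param sd_cut Outlier multiplier (e.g. 5 for height, 7 for BMI).
#' @return Numeric vector aligned with the input.
#' @export
phenotype_prep <- function(phenotype, covariates = NULL, group = NULL,
                           sd_cut = 7) {
  n <- length(phenotype)
  if (is.null(group)) group <- rep(1L, n)
  stopifnot(length(group) == n, sd_cut > 0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  out <- rep(NA_real_, n)
  for (g in unique(group[!is.na(phenotype)])) {
    idx <- which(group == g & !is.na(phenotype))
    if (length(idx) < 3L) stop("phenotype group with fewer than 3 non-missing values")
    x <- phenotype[idx]
    mu <- mean(x); s <- stats::sd(x)
    keep <- if (s > 0) abs(x - mu) <= sd_cut * s else rep(TRUE, length(x))
    idx <- idx[keep]
    if (length(idx) < 3L) stop("phenotype group with fewer than 3 non-missing values after outlier removal")
    x <- phenotype[idx]
    if (!is.null(covariates)) {
      x <- stats::lm.fit(cbind(1, covariates[idx, , drop = FALSE]), x)$residuals
    }
    out[idx] <- rank_inverse_normal(x)
  }
  out
}
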