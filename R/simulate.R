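# Two-population genotype/phenotype simulator with known ground truth.
#
# The generator emulates the features of a two-ancestry GWAS cohort that the
# downstream estimators are sensitive to: Balding-Nichols allele-frequency
# divergence between the populations, within-population LD in blocks, polygenic
# causal effects that are bivariate-normal across populations with a known
# correlation, and population-specific heritabilities. Optional per-individual
# admixture and uniform genotype missingness are available for QC testing.

#' Describe a two-population genotype model
#'
#' @param n_pop1,n_pop2 Number of diploid individuals per population.
#' @param m Number of SNPs.
#' @param fst_target Balding-Nichols divergence parameter F in (0, 1); the
#'   expected per-SNP fixation index between the two populations.
#' @param ancestral_maf_range Range `(lo, hi)` in (0, 0.5] from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param ld_block_size Number of adjacent SNPs per LD block; blocks are
#'   mutually independent.
#' @param ld_rho Latent-Gaussian correlation between adjacent SNPs within a
#'   block, in [0, 1). The realised genotype correlation is monotone in
#'   `ld_rho` but attenuated by dichotomisation.
#' @param admix_fraction Optional admixture for population 2: a single fraction
#'   in [0, 1], a vector of per-individual fractions of population-1 ancestry,
#'   or a function `n -> fractions`. `NULL` (default) disables admixture.
#' @param missing_rate Uniform genotype missingness rate (default 0).
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_pop1, n_pop2, m, fst_target = 0.1,
                             ancestral_maf_range = c(0.1, 0.5),
                             ld_block_size = 20L, ld_rho = 0.6,
                             admix_fraction = NULL, missing_rate = 0) {
  stopifnot(n_pop1 >= 1, n_pop2 >= 1, m >= 1, ld_block_size >= 1)
  stop_if_not_scalar_prob(fst_target, "fst_target", open_left = TRUE, open_right = TRUE)
  stop_if_not_scalar_prob(ld_rho, "ld_rho", open_right = TRUE)
  stop_if_not_scalar_prob(missing_rate, "missing_rate")
  stopifnot(length(ancestral_maf_range) == 2L,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2])
  structure(list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
                 m = as.integer(m), fst_target = fst_target,
                 ancestral_maf_range = ancestral_maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 admix_fraction = admix_fraction, missing_rate = missing_rate),
            class = "population_model")
}

#' Describe a trait architecture shared by two populations
#'
#' @param m_causal Number of causal SNPs.
#' @param rg_true Correlation of causal-variant effects across populations,
#'   in [-1, 1].
#' @param h2_pop1,h2_pop2 Narrow-sense SNP heritability per population, in [0, 1].
#' @param effect_scale `"standardized"` (effects act on standardised genotypes;
#'   matches the GRM-based REML model) or `"per-allele"` (effects act on raw
#'   allele counts; natural for the summary-statistics branch).
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(m_causal, rg_true = 0.75, h2_pop1 = 0.5,
                               h2_pop2 = 0.4,
                               effect_scale = c("standardized", "per-allele")) {
  stopifnot(m_causal >= 1, abs(rg_true) <= 1)
  stop_if_not_scalar_prob(h2_pop1, "h2_pop1")
  stop_if_not_scalar_prob(h2_pop2, "h2_pop2")
  structure(list(m_causal = as.integer(m_causal), rg_true = rg_true,
                 h2_pop1 = h2_pop1, h2_pop2 = h2_pop2,
                 effect_scale = match.arg(effect_scale)),
            class = "trait_architecture")
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency p is drawn uniformly from
#' `ancestral_maf_range`; each population's frequency is then drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `fst_target`, so that the
#' across-population variance of the drawn frequencies is F p(1-p).
#'
#' @param m Number of SNPs.
#' @param fst_target Divergence parameter F in (0, 1).
#' @param ancestral_maf_range Range of the uniform ancestral frequency draw.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `p_anc`, `p1`, `p2` (frequencies of the
#'   counted allele in the ancestral population and the two descendants).
#'   Frequencies are clamped to `[1e-4, 1 - 1e-4]` so downstream
#'   standardisation is always defined.
#' @export
draw_allele_frequencies <- function(m, fst_target,
                                    ancestral_maf_range = c(0.1, 0.5),
                                    seed = NULL) {
  stop_if_not_scalar_prob(fst_target, "fst_target", open_left = TRUE, open_right = TRUE)
  with_seed(seed, {
    p <- stats::runif(m, ancestral_maf_range[1], ancestral_maf_range[2])
    if (any(p <= 0 | p >= 1)) stop("degenerate Beta parameters: ancestral p must be in (0, 1)")
    k <- (1 - fst_target) / fst_target
    p1 <- stats::rbeta(m, p * k, (1 - p) * k)
    p2 <- stats::rbeta(m, p * k, (1 - p) * k)
    clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
    data.frame(p_anc = p, p1 = clamp(p1), p2 = clamp(p2))
  })
}

# Simulate n_hap haplotypes for one LD block: latent Gaussian AR(1) with
# adjacent correlation rho, thresholded at each SNP's allele frequency.
sim_block_haplotypes <- function(n_hap, p_block, rho) {
  b <- length(p_block)
  Z <- matrix(stats::rnorm(n_hap * b), n_hap, b)
  if (rho > 0 && b > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:b) Z[, j] <- rho * Z[, j - 1L] + s * Z[, j]
  }
  # carrier iff latent value below the frequency quantile -> P(carrier) = p
  H <- sweep(Z, 2L, stats::qnorm(p_block), "<")
  storage.mode(H) <- "integer"
  H
}

#' Simulate genotypes for two populations with block LD
#'
#' Haplotypes are generated per population from a latent-Gaussian AR(1) process
#' within blocks of `ld_block_size` adjacent SNPs (blocks are independent), and
#' thresholded at each SNP's population allele frequency; two haplotypes are
#' summed to a diploid genotype coded as the count of the counted (A2) allele.
#' With admixture enabled, each haplotype block of a population-2 individual
#' descends from population 1 with that individual's admixture fraction.
#'
#' @param freqs Data frame from [draw_allele_frequencies()].
#' @param model A [population_model()].
#' @param seed Optional integer seed.
#' @return A `genotype_dataset`: list with `genotypes` (n x m integer matrix,
#'   `NA` for missing), `snp_table`, `sample_table`, and `truth` (true
#'   frequencies; effects filled in by [simulate_phenotypes()]).
#' @export
simulate_genotypes <- function(freqs, model, seed = NULL) {
  stopifnot(inherits(model, "population_model"),
            nrow(freqs) == model$m,
            all(freqs$p1 > 0 & freqs$p1 < 1), all(freqs$p2 > 0 & freqs$p2 < 1))
  m <- model$m
  n1 <- model$n_pop1; n2 <- model$n_pop2; n <- n1 + n2
  with_seed(seed, {
    alpha <- rep(0, n2)  # population-1 ancestry fraction of pop-2 individuals
    if (!is.null(model$admix_fraction)) {
      af <- model$admix_fraction
      alpha <- if (is.function(af)) af(n2) else rep_len(af, n2)
      stopifnot(all(alpha >= 0 & alpha <= 1))
    }
    G <- matrix(0L, n, m)
    if (model$ld_rho == 0 && all(alpha == 0)) {
      # LD-free fast path: direct binomial draws per population
      G[seq_len(n1), ] <- matrix(
        stats::rbinom(n1 * m, 2L, rep(freqs$p1, each = n1)), n1, m)
      G[n1 + seq_len(n2), ] <- matrix(
        stats::rbinom(n2 * m, 2L, rep(freqs$p2, each = n2)), n2, m)
      blocks <- list()
    } else {
      blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% model$ld_block_size)
    }
    for (idx in blocks) {
      # two haplotypes per individual, drawn as independent rows
      hap_a <- sim_block_haplotypes(2L * n1, freqs$p1[idx], model$ld_rho)
      G[seq_len(n1), idx] <- hap_a[seq_len(n1), , drop = FALSE] +
        hap_a[n1 + seq_len(n1), , drop = FALSE]
      hap_b2 <- sim_block_haplotypes(2L * n2, freqs$p2[idx], model$ld_rho)
      if (any(alpha > 0)) {
        hap_b1 <- sim_block_haplotypes(2L * n2, freqs$p1[idx], model$ld_rho)
        src1 <- stats::runif(2L * n2) < rep(alpha, 2L)
        hap_b2[src1, ] <- hap_b1[src1, , drop = FALSE]
      }
      G[n1 + seq_len(n2), idx] <- hap_b2[seq_len(n2), , drop = FALSE] +
        hap_b2[n2 + seq_len(n2), , drop = FALSE]
    }
    if (model$missing_rate > 0) {
      miss <- stats::runif(length(G)) < model$missing_rate
      G[miss] <- NA_integer_
    }
    snp_table <- data.frame(
      id = sprintf("snp%d", seq_len(m)), chr = 1L,
      pos = seq_len(m) * 1000L,  # 1 kb spacing on one chromosome
      allele1 = "G", allele2 = "A", stringsAsFactors = FALSE)
    sample_table <- data.frame(
      fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
      pop = rep(c("pop1", "pop2"), c(n1, n2)),
      sex = rep_len(c(1L, 2L), n),
      admix = c(rep(0, n1), alpha), stringsAsFactors = FALSE)
    new_genotype_dataset(G, snp_table, sample_table,
                         truth = list(p1 = freqs$p1, p2 = freqs$p2,
                                      p_anc = freqs$p_anc))
  })
}

new_genotype_dataset <- function(genotypes, snp_table, sample_table, truth = NULL) {
  stopifnot(nrow(genotypes) == nrow(sample_table),
            ncol(genotypes) == nrow(snp_table),
            !anyDuplicated(paste(sample_table$fid, sample_table$iid)))
  ok <- is.na(genotypes) | (genotypes >= 0L & genotypes <= 2L)
  if (!all(ok)) stop("genotype values must be in {0, 1, 2} or NA")
  by_chr <- split(snp_table$pos, snp_table$chr)
  if (!all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1)))) {
    stop("SNP positions must be strictly increasing within chromosome")
  }
  structure(list(genotypes = genotypes, snp_table = snp_table,
                 sample_table = sample_table, truth = truth),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  print(table(x$sample_table$pop))
  invisible(x)
}

#' Subset a genotype dataset by SNPs or samples
#'
#' @param dataset A `genotype_dataset`.
#' @param snps,samples Integer or logical index vectors.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset_snps <- function(dataset, snps) {
  idx <- if (is.logical(snps)) which(snps) else as.integer(snps)
  truth <- dataset$truth
  if (!is.null(truth)) {
    truth <- lapply(truth, function(v) {
      if (is.matrix(v)) v[idx, , drop = FALSE]
      else if (length(v) == ncol(dataset$genotypes)) v[idx] else v
    })
  }
  new_genotype_dataset(dataset$genotypes[, idx, drop = FALSE],
                       dataset$snp_table[idx, , drop = FALSE],
                       dataset$sample_table, truth)
}

#' @rdname subset_snps
#' @export
subset_samples <- function(dataset, samples) {
  idx <- if (is.logical(samples)) which(samples) else as.integer(samples)
  new_genotype_dataset(dataset$genotypes[idx, , drop = FALSE],
                       dataset$snp_table,
                       dataset$sample_table[idx, , drop = FALSE],
                       dataset$truth)
}

#' Draw correlated per-SNP causal effects for two populations
#'
#' `m_causal` causal SNPs are chosen uniformly at random; their effect pairs
#' are drawn from a bivariate normal with unit variances and correlation
#' `rg_true`. Non-causal SNPs have effect zero in both populations.
#'
#' @param architecture A [trait_architecture()].
#' @param m Total number of SNPs.
#' @param seed Optional integer seed.
#' @return An `m` x 2 matrix of effects with attribute `causal` (indices).
#' @export
draw_effects <- function(architecture, m, seed = NULL) {
  stopifnot(inherits(architecture, "trait_architecture"))
  mc <- architecture$m_causal
  if (mc > m) stop("m_causal exceeds the number of SNPs")
  rg <- architecture$rg_true
  with_seed(seed, {
    causal <- sort(sample.int(m, mc))
    z1 <- stats::rnorm(mc)
    if (abs(rg) == 1) {
      z2 <- rg * z1
    } else {
      z2 <- rg * z1 + sqrt(1 - rg^2) * stats::rnorm(mc)
    }
    beta <- matrix(0, m, 2L)
    beta[causal, 1L] <- z1
    beta[causal, 2L] <- z2
    attr(beta, "causal") <- causal
    beta
  })
}

#' Simulate phenotypes from genotypes and causal effects
#'
#' Per population, the genetic value is the product of (standardised or raw,
#' depending on the architecture's `effect_scale`) genotypes and that
#' population's effect column, rescaled so its realised variance equals the
#' target heritability; independent Gaussian noise with variance 1 - h2 is
#' added, so the phenotype variance is approximately 1.
#'
#' @param dataset A `genotype_dataset` with true frequencies in `$truth`.
#' @param effects Matrix from [draw_effects()].
#' @param architecture A [trait_architecture()] (supplies h2 per population and
#'   the effect scale).
#' @param seed Optional integer seed.
#' @return A data.frame `fid, iid, pheno` with attributes `genetic_values` and
#'   `beta_scaled` (the per-population effects after heritability scaling, on
#'   the scale they were applied).
#' @export
simulate_phenotypes <- function(dataset, effects, architecture, seed = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(architecture, "trait_architecture"),
            nrow(effects) == ncol(dataset$genotypes))
  pops <- dataset$sample_table$pop
  stopifnot(all(pops %in% c("pop1", "pop2")))
  h2 <- c(pop1 = architecture$h2_pop1, pop2 = architecture$h2_pop2)
  truth_p <- list(pop1 = dataset$truth$p1, pop2 = dataset$truth$p2)
  with_seed(seed, {
    n <- nrow(dataset$genotypes)
    y <- numeric(n); g_all <- numeric(n)
    beta_scaled <- matrix(0, nrow(effects), 2L,
                          dimnames = list(NULL, c("pop1", "pop2")))
    for (k in c("pop1", "pop2")) {
      idx <- which(pops == k)
      if (!length(idx)) next
      X <- dataset$genotypes[idx, , drop = FALSE]
      kcol <- if (k == "pop1") 1L else 2L
      if (architecture$effect_scale == "standardized") {
        Z <- standardize_genotypes(X, truth_p[[k]])
      } else {
        Z <- X
        Z[is.na(Z)] <- 0
      }
      g <- drop(Z %*% effects[, kcol])
      vg <- stats::var(g)
      h2k <- h2[[k]]
      if (h2k > 0 && vg == 0) stop("zero genetic variance with h2 > 0")
      scale_k <- if (h2k > 0) sqrt(h2k / vg) else 0
      g <- g * scale_k
      beta_scaled[, kcol] <- effects[, kcol] * scale_k
      e <- stats::rnorm(length(idx), 0, sqrt(1 - h2k))
      y[idx] <- g + e
      g_all[idx] <- g
    }
    out <- data.frame(fid = dataset$sample_table$fid,
                      iid = dataset$sample_table$iid,
                      pheno = y, stringsAsFactors = FALSE)
    attr(out, "genetic_values") <- g_all
    attr(out, "beta_scaled") <- beta_scaled
    out
  })
}

#' Simulate a complete two-population cohort
#'
#' Convenience wrapper chaining [draw_allele_frequencies()],
#' [simulate_genotypes()], [draw_effects()] and [simulate_phenotypes()], with
#' deterministic per-stage child seeds derived from `seed`.
#'
#' @param model A [population_model()].
#' @param architecture A [trait_architecture()].
#' @param seed Integer seed.
#' @return List with `dataset`, `phenotype`, `effects`, `freqs`.
#' @export
simulate_cohort <- function(model, architecture, seed) {
  freqs <- draw_allele_frequencies(model$m, model$fst_target,
                                   model$ancestral_maf_range,
                                   seed = child_seed(seed, "freqs"))
  ds <- simulate_genotypes(freqs, model, seed = child_seed(seed, "genotypes"))
  beta <- draw_effects(architecture, model$m, seed = child_seed(seed, "effects"))
  ph <- simulate_phenotypes(ds, beta, architecture,
                            seed = child_seed(seed, "phenotypes"))
  ds$truth$beta <- beta
  ds$truth$beta_scaled <- attr(ph, "beta_scaled")
  ds$truth$causal <- attr(beta, "causal")
  list(dataset = ds, phenotype = ph, effects = beta, freqs = freqs)
}
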