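# Independent oracles and small fixture builders used across the suite.

# Exact Hardy-Weinberg probabilities by direct multinomial enumeration with
# choose(); independent of the package's recurrence implementation.
hwe_exact_brute <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  na <- 2 * n_hom1 + n_het          # copies of allele a
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    r <- (na - h) / 2
    c <- n - h - r
    lchoose(n, r) + lchoose(n - r, h) + h * log(2) -
      (lchoose(2 * n, na))
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Direct REML log-likelihood of a linear-covariance model, written plainly
# with solve()/determinant(); used as the objective for derivative-free
# maximisation, independent of the AI-REML iteration path.
reml_loglik_direct <- function(theta, K, y, X) {
  V <- Reduce(`+`, Map(`*`, K, theta))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) return(-Inf)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (sum(log(ev)) +
          as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
          as.numeric(t(y) %*% P %*% y))
}

# Generic delta-method sampling variance/covariance of rg = C / sqrt(V1 V2):
# gradient of the ratio times the sampling covariance times the gradient.
# Independent of the term-by-term bracket implementation in the package.
rg_delta_oracle <- function(estimates, vcov) {
  grad_of <- function(i) {
    V1 <- estimates[i[1]]; V2 <- estimates[i[2]]; C <- estimates[i[3]]
    g <- numeric(6)
    g[i[1]] <- -C / (2 * V1 * sqrt(V1 * V2))
    g[i[2]] <- -C / (2 * V2 * sqrt(V1 * V2))
    g[i[3]] <- 1 / sqrt(V1 * V2)
    g
  }
  g1 <- grad_of(1:3)
  g2 <- grad_of(4:6)
  list(var1 = as.numeric(t(g1) %*% vcov %*% g1),
       var2 = as.numeric(t(g2) %*% vcov %*% g2),
       cov12 = as.numeric(t(g1) %*% vcov %*% g2))
}

# Random PSD matrix with positive variance components on the diagonal scale.
random_psd <- function(d, seed) {
  set.seed(seed)
  M <- matrix(rnorm(d * d), d)
  crossprod(M) / d + diag(0.1, d)
}

# Small two-population cohort for integration-style tests.
small_cohort <- function(seed = 1, n = 150, m = 300, m_causal = 120,
                         rg = 0.7, h2_1 = 0.5, h2_2 = 0.4, fst = 0.1,
                         ld_block = 5, ld_rho = 0.4) {
  model <- population_model(n, n, m, fst_target = fst,
                            ld_block_size = ld_block, ld_rho = ld_rho)
  arch <- trait_architecture(m_causal, rg_true = rg, h2_pop1 = h2_1,
                             h2_pop2 = h2_2)
  simulate_cohort(model, arch, seed = seed)
}

# SNPs polymorphic in both populations (GRM-specific prerequisite).
both_polymorphic <- function(dataset) {
  pops <- dataset$sample_table$pop
  ok <- rep(TRUE, ncol(dataset$genotypes))
  for (k in unique(pops)) {
    p <- colMeans(dataset$genotypes[pops == k, , drop = FALSE], na.rm = TRUE) / 2
    ok <- ok & p > 0 & p < 1
  }
  subset_snps(dataset, which(ok))
}
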