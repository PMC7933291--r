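test_that("Hudson FST evaluates its formula and is calibrated", {
  # direct formula evaluation in the infinite-sample limit
  expect_equal(fst_per_snp(0.1, 1e9, 0.9, 1e9), 0.64 / 0.82, tolerance = 1e-6)
  # no differentiation, large n: estimate is essentially 0
  expect_equal(fst_per_snp(0.3, 1e7, 0.3, 1e7), 0, tolerance = 1e-5)
  # unbiasedness under no differentiation: negative values are possible and
  # the mean over SNPs is about 0
  set.seed(301)
  p <- runif(4000, 0.1, 0.5)
  p1 <- rbinom(4000, 400, p) / 400
  p2 <- rbinom(4000, 400, p) / 400
  f <- fst_per_snp(p1, 400, p2, 400)
  expect_true(any(f < 0, na.rm = TRUE))
  expect_lt(abs(mean(f, na.rm = TRUE)), 0.005)
  # undefined denominator -> NA with a message
  expect_message(f0 <- fst_per_snp(c(0, 0.5), 100, c(0, 0.5), 100),
                 "undefined")
  expect_true(is.na(f0[1]) && !is.na(f0[2]))
})

test_that("genome-wide mean FST uses the ratio of averages", {
  fr <- draw_allele_frequencies(20000, fst_target = 0.15,
                                ancestral_maf_range = c(0.1, 0.5), seed = 320)
  # at effectively infinite sample size the ratio of averages recovers F,
  # while the arithmetic mean of per-SNP ratios does not
  fm <- fst_mean(fr$p1, 1e9, fr$p2, 1e9)
  expect_equal(fm, 0.15, tolerance = 0.05)
  per_snp <- fst_per_snp(fr$p1, 1e9, fr$p2, 1e9)
  expect_gt(abs(mean(per_snp) - 0.15), abs(fm - 0.15))
})

test_that("Weir-Cockerham FST agrees with Hudson at equal sample sizes", {
  set.seed(302)
  fr <- draw_allele_frequencies(2000, 0.1, c(0.1, 0.5), seed = 302)
  p1 <- rbinom(2000, 1000, fr$p1) / 1000
  p2 <- rbinom(2000, 1000, fr$p2) / 1000
  fh <- fst_per_snp(p1, 1000, p2, 1000)
  fw <- fst_per_snp(p1, 1000, p2, 1000, estimator = "wc")
  expect_gt(cor(fh, fw, use = "complete.obs"), 0.99)
  expect_equal(mean(fw, na.rm = TRUE), mean(fh, na.rm = TRUE), tolerance = 0.15)
})

test_that("LD scores equal 1 for isolated or independent SNPs and grow with LD", {
  # single SNP: self term only
  set.seed(303)
  x <- matrix(rbinom(200, 2, 0.4), 100, 2)
  ell <- ld_scores(x, positions = c(1e6, 5e7))   # far apart: no neighbours
  expect_equal(ell, c(1, 1), tolerance = 1e-12)
  # independent SNPs: the adjustment removes the sampling inflation
  model <- population_model(400, 10, 2000, ld_block_size = 1, ld_rho = 0)
  fr <- draw_allele_frequencies(2000, 0.1, c(0.2, 0.5), seed = 304)
  ds <- simulate_genotypes(fr, model, seed = 305)
  G1 <- ds$genotypes[ds$sample_table$pop == "pop1", ]
  ell <- ld_scores(G1, ds$snp_table$pos, window_kb = 100)
  expect_equal(mean(ell), 1, tolerance = 0.05)
  # monotone in the block correlation
  means <- sapply(c(0.2, 0.5, 0.8), function(rho) {
    m <- population_model(400, 10, 300, ld_block_size = 10, ld_rho = rho)
    frb <- draw_allele_frequencies(300, 0.1, c(0.2, 0.5), seed = 306)
    d <- simulate_genotypes(frb, m, seed = 307)
    mean(ld_scores(d$genotypes[d$sample_table$pop == "pop1", ],
                   d$snp_table$pos, window_kb = 50))
  })
  expect_true(all(diff(means) > 0))
})

test_that("LDCV is the two-value CV and is scale invariant", {
  expect_equal(ldcv(2, 1), 1 / (sqrt(2) * 1.5), tolerance = 1e-12)
  expect_equal(ldcv(3, 3), 0)
  expect_equal(ldcv(2 * 7, 1 * 7), ldcv(2, 1), tolerance = 1e-12)
  expect_error(ldcv(0, 0), "positive")
})

test_that("joint bins expose the full factorial bin space", {
  set.seed(308)
  m <- 5000
  p1 <- runif(m, 0.05, 0.95); p2 <- runif(m, 0.05, 0.95)
  l1 <- rexp(m) + 1; l2 <- rexp(m) + 1
  b <- make_bins(p1, p2, l1, l2, n_freq_bins = 125, n_ld_bins = 4)
  expect_equal(attr(b, "n_bins_possible"), 250000)
  b2 <- make_bins(p1, p2, l1, l2, n_freq_bins = 20, n_ld_bins = 25)
  expect_equal(attr(b2, "n_bins_possible"), 250000)
  b1 <- make_bins(p1, p2, l1, l2, n_freq_bins = 1, n_ld_bins = 1)
  expect_true(all(b1 == b1[1]))
  # frequency axis 1 uses MAF: p and 1-p land in the same bin
  bb <- make_bins(c(0.25, 0.75, 0.25, 0.75), c(0.5, 0.5, 0.5, 0.5),
                  rep(1, 4), rep(1, 4), n_freq_bins = 2, n_ld_bins = 1)
  expect_equal(bb[1], bb[2])
})

test_that("within-bin splitting halves each bin by the metric", {
  b <- rep(1L, 4)
  g <- split_within_bins(b, c(0.2, 0.4, 0.1, 0.3), seed = 1)
  expect_equal(as.character(g), c("low", "high", "low", "high"))
  # odd bin: median goes to either side, reproducibly under the seed
  b3 <- rep(1L, 3)
  g3a <- split_within_bins(b3, c(0.1, 0.2, 0.3), seed = 5)
  g3b <- split_within_bins(b3, c(0.1, 0.2, 0.3), seed = 5)
  expect_identical(g3a, g3b)
  expect_equal(as.character(g3a)[1], "low")
  expect_equal(as.character(g3a)[3], "high")
  expect_true(abs(sum(g3a == "low") - sum(g3a == "high")) == 1)
  # randomisation actually uses both outcomes across seeds
  mids <- vapply(1:40, function(s) {
    as.character(split_within_bins(b3, c(0.1, 0.2, 0.3), seed = s))[2]
  }, character(1))
  expect_true(all(c("low", "high") %in% mids))
  # group sizes are balanced within 1 per bin
  set.seed(309)
  bins <- sample.int(50, 1000, replace = TRUE)
  met <- runif(1000)
  g <- split_within_bins(bins, met, seed = 7)
  per_bin <- table(bins, g)
  expect_true(all(abs(per_bin[, "low"] - per_bin[, "high"]) <= 1))
})

test_that("stratification table is complete and deterministic", {
  co <- small_cohort(seed = 310, n = 120, m = 300, m_causal = 100)
  ds <- both_polymorphic(co$dataset)
  st1 <- snp_strata(ds, metric = "fst", n_freq_bins = 5, n_ld_bins = 2, seed = 3)
  st2 <- snp_strata(ds, metric = "fst", n_freq_bins = 5, n_ld_bins = 2, seed = 3)
  expect_identical(st1, st2)
  expect_true(all(!is.na(st1$group)))
  expect_equal(attr(st1, "n_bins_possible"), 5^2 * 2^2)
  expect_lt(abs(sum(st1$group == "low") - sum(st1$group == "high")),
            length(unique(st1$bin)) + 1)
  # high group has systematically larger FST
  expect_gt(mean(st1$fst[st1$group == "high"]), mean(st1$fst[st1$group == "low"]))
})

test_that("two-component stratified fit decomposes the heritability", {
  co <- small_cohort(seed = 311, n = 250, m = 400, m_causal = 160)
  ds <- both_polymorphic(co$dataset)
  y <- co$phenotype$pheno
  st <- snp_strata(ds, metric = "fst", n_freq_bins = 4, n_ld_bins = 2, seed = 4)
  tc <- two_component_fit(ds, st$group, y)
  expect_s3_class(tc$moments, "component_moments")
  expect_length(tc$fit$estimates, 8)
  # total h2 consistent with the single-component fit
  single <- bivariate_greml(y, ds$sample_table$pop, compute_grm(ds, "specific"))
  for (i in 1:2) {
    se <- sqrt(single$h2$se[i]^2 + 1e-12)
    expect_lt(abs(single$h2$h2[i] - tc$fit$h2$h2[i]), 3 * 3 * se)
  }
})

test_that("a stratum with no causal SNPs shows no heritability", {
  model <- population_model(250, 250, 300, fst_target = 0.1,
                            ld_block_size = 1, ld_rho = 0)
  arch <- trait_architecture(100, rg_true = 0.8, h2_pop1 = 0.5, h2_pop2 = 0.5)
  fr <- draw_allele_frequencies(300, 0.1, c(0.1, 0.5), seed = 312)
  ds <- simulate_genotypes(fr, model, seed = 313)
  # causal SNPs confined to the first half
  beta <- draw_effects(arch, 300, seed = 314)
  causal <- attr(beta, "causal")
  beta[causal[causal > 150], ] <- 0
  ph <- simulate_phenotypes(ds, beta, arch, seed = 315)
  groups <- factor(rep(c("low", "high"), each = 150), levels = c("low", "high"))
  ds <- both_polymorphic(ds)
  groups <- groups[match(ds$snp_table$id, sprintf("snp%d", 1:300))]
  tc <- two_component_fit(ds, groups, ph$pheno)
  est <- tc$fit$estimates
  vc <- tc$fit$sampling_cov
  for (nm in c("Vg1_high", "Vg2_high")) {
    expect_lt(est[nm], max(2 * sqrt(vc[nm, nm]), 0.1))
  }
})
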