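test_that("the Hardy-Weinberg exact test matches direct enumeration", {
  cases <- list(c(50, 25, 25), c(60, 0, 0), c(10, 45, 45), c(3, 1, 0),
                c(0, 30, 30), c(21, 10, 9))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_exact_brute(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
  # the modal configuration has exact p of 1
  expect_equal(hwe_exact_test(50, 25, 25), 1, tolerance = 1e-12)
  # all-heterozygote sample at frequency 0.5 is wildly out of equilibrium
  expect_lt(hwe_exact_test(60, 0, 0), 0.001)
})

test_that("SNP QC filters in the fixed order missingness -> MAF -> HWE", {
  set.seed(71)
  n <- 100
  g_ok <- rbinom(n, 2, 0.4)
  g_miss <- g_ok; g_miss[1:10] <- NA             # 10% missing
  g_rare <- rep(0L, n)                            # monomorphic, MAF 0
  g_hwe <- rep(1L, n)                             # all het
  G <- cbind(g_ok, g_miss, g_rare, g_hwe)
  ds <- xpgreml:::new_genotype_dataset(
    G, data.frame(id = paste0("s", 1:4), chr = 1L, pos = (1:4) * 10L,
                  allele1 = "G", allele2 = "A"),
    data.frame(fid = paste0("F", 1:n), iid = paste0("I", 1:n),
               pop = "pop1", sex = 1L, admix = 0))
  out <- snp_qc(ds, qc_thresholds(snp_missing_max = 0.05, maf_min = 0.01,
                                  hwe_p_min = 0.001))
  expect_identical(out$removed$missingness, "s2")
  expect_identical(out$removed$maf, "s3")
  expect_identical(out$removed$hwe, "s4")
  expect_identical(out$dataset$snp_table$id, "s1")
  # idempotence
  again <- snp_qc(out$dataset, qc_thresholds())
  expect_identical(again$dataset$snp_table$id, out$dataset$snp_table$id)
})

test_that("sample QC removes on strict call-rate threshold", {
  G <- rbind(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L),
             c(NA, NA, NA, NA, NA, 1L, 2L, 0L, 1L, 2L),   # 50% call rate
             c(NA, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L))   # exactly 90%
  ds <- xpgreml:::new_genotype_dataset(
    G, data.frame(id = paste0("s", 1:10), chr = 1L, pos = (1:10) * 10L,
                  allele1 = "G", allele2 = "A"),
    data.frame(fid = paste0("F", 1:3), iid = paste0("I", 1:3), pop = "pop1",
               sex = 1L, admix = 0))
  out <- sample_qc(ds, qc_thresholds(sample_callrate_min = 0.9))
  expect_identical(out$removed, "I2")
  # exactly at the threshold is retained (strict "<" removal)
  expect_identical(out$dataset$sample_table$iid, c("I1", "I3"))
  # no missingness: identity
  ds_clean <- subset_samples(ds, 1L)
  expect_identical(sample_qc(ds_clean)$dataset$genotypes, ds_clean$genotypes)
})

test_that("PC outlier filtering flags displaced samples", {
  set.seed(72)
  pcs <- cbind(rnorm(100), rnorm(100))
  keep <- pc_outlier_filter(pcs, reference_mean = c(0, 0),
                            reference_sd = c(1, 1), sd_cut = 6)
  expect_true(all(keep))
  pcs[7, 2] <- 7
  keep <- pc_outlier_filter(pcs, reference_mean = c(0, 0),
                            reference_sd = c(1, 1), sd_cut = 6)
  expect_identical(which(!keep), 7L)
  expect_error(pc_outlier_filter(pcs, c(0, 0), c(0, 1)), "zero reference")
})

test_that("strongly admixed individuals are PC outliers relative to their population", {
  model <- population_model(600, 300, 500, fst_target = 0.15,
                            ld_block_size = 1, ld_rho = 0,
                            admix_fraction = function(n) {
                              c(rep(0, n - 15), rep(0.8, 15))
                            })
  fr <- draw_allele_frequencies(500, 0.15, c(0.1, 0.5), seed = 73)
  ds <- simulate_genotypes(fr, model, seed = 74)
  i2 <- which(ds$sample_table$pop == "pop2")
  ds2 <- subset_samples(ds, i2)
  grm <- compute_grm(ds2, mode = "average")
  pcs <- compute_pcs(grm, 2)
  admixed <- ds2$sample_table$admix > 0
  ref_mean <- apply(pcs[!admixed, 1:2], 2, mean)
  ref_sd <- apply(pcs[!admixed, 1:2], 2, sd)
  keep <- pc_outlier_filter(pcs, ref_mean, ref_sd, sd_cut = 6)
  expect_gt(mean(!keep[admixed]), 0.8)       # most admixed flagged
  expect_lt(mean(!keep[!admixed]), 0.05)
})

test_that("relatedness pruning is greedy, deterministic and sufficient", {
  A <- diag(6)
  expect_identical(relatedness_prune(A, 0.05), 1:6)
  A[1, 2] <- A[2, 1] <- 0.3    # one pair: remove exactly one (tie -> index 1)
  expect_identical(relatedness_prune(A, 0.05), 2:6)
  B <- diag(6)
  B[1:4, 1:4] <- 0.2; diag(B) <- 1             # 4-clique: keep one of the four
  kept <- relatedness_prune(B, 0.05)
  expect_identical(kept, 4:6)
  out <- B[kept, kept]
  expect_true(all(out[upper.tri(out)] <= 0.05))
  # brute-force check on random small graphs: result is always a valid cover
  # and no larger than necessary by more than the greedy bound
  set.seed(75)
  for (rep in 1:20) {
    n <- 6
    M <- diag(n)
    pairs <- which(upper.tri(M), arr.ind = TRUE)
    hot <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    M[hot] <- 0.2; M[hot[, 2:1, drop = FALSE]] <- 0.2
    kept <- relatedness_prune(M, 0.05)
    sub <- M[kept, kept, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] <= 0.05))
    # brute force the maximum retainable set
    best <- 0
    for (msk in 0:(2^n - 1)) {
      sel <- which(bitwAnd(msk, 2^(0:(n - 1))) > 0)
      s <- M[sel, sel, drop = FALSE]
      if (all(s[upper.tri(s)] <= 0.05)) best <- max(best, length(sel))
    }
    expect_gte(length(kept), best - 2)         # greedy is near-optimal here
  }
})

test_that("phenotype preparation inverse-normalises within groups", {
  out <- phenotype_prep(c(1.2, 5.0, 3.3))
  expect_equal(out, qnorm(c(1, 5, 3) / 6), tolerance = 1e-12)
  expect_equal(out[3], 0)
  # an extreme outlier is excluded before the transform
  x <- c(rnorm(50), 1000)
  out <- phenotype_prep(x, sd_cut = 5)
  expect_true(is.na(out[51]))
  expect_equal(mean(out, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(out, na.rm = TRUE), 1, tolerance = 0.1)
  # invariance to monotone transforms of the input
  set.seed(76)
  x <- rlnorm(200)
  expect_equal(phenotype_prep(x, sd_cut = 100),
               phenotype_prep(log(x), sd_cut = 100), tolerance = 1e-12)
  # covariate adjustment happens inside each group
  grp <- rep(c("m", "f"), each = 100)
  covar <- rnorm(200)
  y <- 2 * covar + rnorm(200)
  out <- phenotype_prep(y, covariates = covar, group = grp, sd_cut = 100)
  expect_lt(abs(cor(out[grp == "m"], covar[grp == "m"])), 0.25)
  expect_error(phenotype_prep(c(1, 2)), "fewer than 3")
})
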