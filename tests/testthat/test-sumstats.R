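test_that("the association scan is calibrated under the null and recovers effects", {
  # null trait: uniform p-values
  model <- population_model(600, 10, 3000, ld_block_size = 1, ld_rho = 0)
  fr <- draw_allele_frequencies(3000, 0.1, c(0.1, 0.5), seed = 501)
  ds <- simulate_genotypes(fr, model, seed = 502)
  ds1 <- subset_samples(ds, which(ds$sample_table$pop == "pop1"))
  set.seed(501)
  y_null <- rnorm(600)
  ss <- gwas_scan(ds1, y_null)
  expect_gt(ks.test(ss$p, "punif")$p.value, 0.01)
  expect_true(all(ss$se > 0))
  expect_equal(unique(ss$N), 600)
  # effect recovery against the truth sidecar
  co <- small_cohort(seed = 503, n = 800, m = 300, m_causal = 30,
                     h2_1 = 0.5, h2_2 = 0.5, ld_block = 1, ld_rho = 0)
  dsx <- co$dataset
  i1 <- which(dsx$sample_table$pop == "pop1")
  ss1 <- gwas_scan(subset_samples(dsx, i1), co$phenotype$pheno[i1])
  bt <- dsx$truth$beta_scaled[, "pop1"]
  # per-allele truth: standardised effect / sqrt(2p(1-p))
  per_allele <- bt / sqrt(2 * dsx$truth$p1 * (1 - dsx$truth$p1))
  j <- match(ss1$SNP, dsx$snp_table$id)
  z <- (ss1$b - per_allele[j]) / ss1$se
  expect_lt(mean(abs(z) > 3), 0.02)
})

test_that("a perfectly linear single-SNP fit has vanishing error", {
  G <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L), 8, 1)
  ds <- xpgreml:::new_genotype_dataset(
    G, data.frame(id = "s1", chr = 1L, pos = 1L, allele1 = "G", allele2 = "A"),
    data.frame(fid = paste0("F", 1:8), iid = paste0("I", 1:8), pop = "pop1",
               sex = 1L, admix = 0))
  y <- 0.5 + 2 * as.numeric(G)
  ss <- gwas_scan(ds, y)
  expect_equal(ss$b, 2, tolerance = 1e-10)
  expect_lt(ss$se, 1e-6)
  expect_lt(ss$p, 1e-12)
})

test_that(".ma files round-trip and are validated", {
  ss <- data.frame(SNP = c("s1", "s2"), A1 = c("A", "A"), A2 = c("G", "G"),
                   freq = c(0.3, 0.4), b = c(0.1, -0.2), se = c(0.05, 0.04),
                   p = c(0.04, 1e-6), N = 100L, stringsAsFactors = FALSE)
  path <- file.path(withr::local_tempdir(), "test.ma")
  write_ma(ss, path)
  back <- read_ma(path)
  expect_equal(back$b, ss$b)
  expect_s3_class(back, "sumstats")
  bad <- ss; bad$se[1] <- 0
  write_ma(bad, path)
  expect_error(read_ma(path), "se must be positive")
})

test_that("greedy clumping reproduces hand-worked traces", {
  # 3 SNPs: SNP3 strongest, SNP1 in LD with it within 1 Mb, SNP2 isolated
  set.seed(504)
  x3 <- rbinom(400, 2, 0.4)
  x1 <- x3
  flip <- runif(400) < 0.25                   # r2 about 0.5 with x3
  x1[flip] <- rbinom(sum(flip), 2, 0.4)
  x2 <- rbinom(400, 2, 0.3)
  G <- cbind(x1, x3, x2)                       # position order
  storage.mode(G) <- "integer"
  ds <- xpgreml:::new_genotype_dataset(
    G, data.frame(id = c("SNP1", "SNP3", "SNP2"), chr = 1L,
                  pos = c(100000L, 600000L, 50000000L),
                  allele1 = "G", allele2 = "A"),
    data.frame(fid = paste0("F", 1:400), iid = paste0("I", 1:400),
               pop = "pop1", sex = 1L, admix = 0))
  ss <- data.frame(SNP = c("SNP1", "SNP2", "SNP3"), A1 = "A", A2 = "G",
                   freq = 0.4, b = 1, se = 0.1,
                   p = c(1e-10, 1e-9, 1e-12), N = 400L)
  out <- clump(ss, ds, p_threshold = 5e-8, r2_threshold = 0.01,
               window_kb = 1000)
  expect_identical(out$sentinels, c("SNP3", "SNP2"))
  expect_identical(out$clumps$clump, c("SNP3", "SNP2", "SNP3"))
  # all mutually independent: every significant SNP is a sentinel
  ds_ind <- xpgreml:::new_genotype_dataset(
    cbind(x2, rbinom(400, 2, 0.4), rbinom(400, 2, 0.2)),
    data.frame(id = paste0("I", 1:3), chr = 1L,
               pos = c(1e5L, 2e5L, 3e5L), allele1 = "G", allele2 = "A"),
    ds$sample_table)
  ss_ind <- data.frame(SNP = paste0("I", 1:3), A1 = "A", A2 = "G", freq = 0.4,
                       b = 1, se = 0.1, p = c(1e-9, 1e-10, 0.5), N = 400L)
  out2 <- clump(ss_ind, ds_ind, 5e-8, 0.01, 1000)
  expect_setequal(out2$sentinels, c("I1", "I2"))
})

test_that("the second clumping round removes long-range LD at 10 Mb", {
  # two round-1 sentinels 5 Mb apart with r2 about 0.02
  set.seed(505)
  n <- 4000
  xa <- rbinom(n, 2, 0.5)
  xb <- xa
  flip <- runif(n) < 0.835
  xb[flip] <- rbinom(sum(flip), 2, 0.5)
  r2 <- cor(xa, xb)^2
  expect_gt(r2, 0.01); expect_lt(r2, 0.05)
  G <- cbind(xa, xb)
  storage.mode(G) <- "integer"
  ds <- xpgreml:::new_genotype_dataset(
    G, data.frame(id = c("A", "B"), chr = 1L, pos = c(1000000L, 6000000L),
                  allele1 = "G", allele2 = "A"),
    data.frame(fid = paste0("F", 1:n), iid = paste0("I", 1:n), pop = "pop1",
               sex = 1L, admix = 0))
  ss <- data.frame(SNP = c("A", "B"), A1 = "A", A2 = "G", freq = 0.5, b = 1,
                   se = 0.1, p = c(1e-12, 1e-9), N = n)
  out <- clump_two_round(ss, ds, 5e-8, 0.01, window_kb = 1000,
                         window2_kb = 10000)
  expect_identical(out$round1$sentinels, c("A", "B"))  # 1 Mb: both survive
  expect_identical(out$sentinels, "A")                 # 10 Mb: weaker removed
})

test_that("split-sample re-estimation is disjoint, seeded and shrinks effects", {
  co <- small_cohort(seed = 506, n = 1200, m = 400, m_causal = 200,
                     h2_1 = 0.3, h2_2 = 0.3, ld_block = 1, ld_rho = 0)
  ds <- co$dataset
  i1 <- which(ds$sample_table$pop == "pop1")
  ds1 <- subset_samples(ds, i1)
  y1 <- co$phenotype$pheno[i1]
  sp <- suppressMessages(
    split_sample_reestimate(ds1, y1, ds$snp_table$id,
                            discovery_fraction = 0.5, seed = 9))
  expect_length(intersect(sp$discovery_idx, sp$estimation_idx), 0)
  expect_equal(sort(c(sp$discovery_idx, sp$estimation_idx)), seq_along(i1))
  sp2 <- suppressMessages(
    split_sample_reestimate(ds1, y1, ds$snp_table$id,
                            discovery_fraction = 0.5, seed = 9))
  expect_identical(sp$discovery_idx, sp2$discovery_idx)
  # winner's curse: SNPs selected for significance in the discovery half
  # shrink when re-estimated in the independent half
  disc_top <- sp$discovery$SNP[order(sp$discovery$p)[1:25]]
  j_d <- match(disc_top, sp$discovery$SNP)
  j_e <- match(disc_top, sp$estimation$SNP)
  expect_gt(mean(abs(sp$discovery$b[j_d])),
            1.3 * mean(abs(sp$estimation$b[j_e])))
})

test_that("r_b corrects the attenuation that estimation noise causes", {
  set.seed(507)
  k <- 500
  reps <- 25
  hits <- 0
  for (r in 1:reps) {
    bt <- MASS::mvrnorm(k, c(0, 0), matrix(c(1, 0.8, 0.8, 1), 2)) * 0.05
    se_a <- runif(k, 0.02, 0.04); se_b <- runif(k, 0.02, 0.04)
    ss_a <- data.frame(SNP = paste0("s", 1:k), A1 = "A", A2 = "G", freq = 0.3,
                       b = bt[, 1] + rnorm(k, 0, se_a), se = se_a, p = 0.5, N = 1000)
    ss_b <- data.frame(SNP = paste0("s", 1:k), A1 = "A", A2 = "G", freq = 0.3,
                       b = bt[, 2] + rnorm(k, 0, se_b), se = se_b, p = 0.5, N = 1000)
    out <- rb_estimate(ss_a, ss_b)
    expect_lt(out$r_naive, out$rb)             # attenuation removed
    if (abs(out$rb - 0.8) <= 2 * out$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.85)
})

test_that("r_b degenerate and edge cases are guarded", {
  set.seed(508)
  k <- 60
  bt <- rnorm(k, 0, 0.08)
  ss_a <- data.frame(SNP = paste0("s", 1:k), A1 = "A", A2 = "G", freq = 0.3,
                     b = bt, se = rep(1e-8, k), p = 0.5, N = 1000)
  ss_b <- ss_a
  ss_b$b <- bt + rnorm(k, 0, 1e-8)
  out <- rb_estimate(ss_a, ss_b)
  expect_equal(out$rb, 1, tolerance = 1e-4)     # noiseless: rb = 1, se ~ 0
  expect_lt(out$se, 1e-3)
  # independent effects: rb near 0
  ss_c <- ss_a
  ss_c$b <- rnorm(k, 0, 0.08); ss_c$se <- rep(0.01, k)
  ss_a2 <- ss_a; ss_a2$se <- rep(0.01, k)
  out0 <- rb_estimate(ss_a2, ss_c)
  expect_lt(abs(out0$rb), 2 * out0$se + 0.3)
  # identical tables are rejected
  expect_error(rb_estimate(ss_a, ss_a), "identical")
  # noise exceeding signal is reported as undefined
  ss_n1 <- ss_a; ss_n1$b <- rnorm(k, 0, 0.01); ss_n1$se <- rep(0.2, k)
  ss_n2 <- ss_a; ss_n2$b <- rnorm(k, 0, 0.01); ss_n2$se <- rep(0.2, k)
  expect_warning(outn <- rb_estimate(ss_n1, ss_n2), "undefined")
  expect_true(is.na(outn$rb))
  expect_error(rb_estimate(ss_a[1:5, ], ss_b[1:5, ]), "at least 10")
})

test_that("r_b is symmetric and allele-flip invariant", {
  set.seed(509)
  k <- 80
  bt <- rnorm(k, 0, 0.06)
  se <- rep(0.02, k)
  ss_a <- data.frame(SNP = paste0("s", 1:k), A1 = "A", A2 = "G", freq = 0.3,
                     b = bt + rnorm(k, 0, se), se = se, p = 0.5, N = 500)
  ss_b <- data.frame(SNP = paste0("s", 1:k), A1 = "A", A2 = "G", freq = 0.35,
                     b = bt + rnorm(k, 0, se), se = se, p = 0.5, N = 500)
  fwd <- rb_estimate(ss_a, ss_b)
  rev <- rb_estimate(ss_b, ss_a)
  expect_equal(fwd$rb, rev$rb, tolerance = 1e-12)
  # flip alleles and effect signs on half the rows of b
  ss_flip <- ss_b
  idx <- 1:40
  ss_flip$A1[idx] <- "G"; ss_flip$A2[idx] <- "A"
  ss_flip$b[idx] <- -ss_flip$b[idx]
  ss_flip$freq[idx] <- 1 - ss_flip$freq[idx]
  out <- rb_estimate(ss_a, ss_flip)
  expect_equal(out$rb, fwd$rb, tolerance = 1e-12)
})

test_that("the same-population negative control recovers r_b near 1", {
  co <- small_cohort(seed = 510, n = 1600, m = 400, m_causal = 25,
                     h2_1 = 0.6, h2_2 = 0.6, ld_block = 1, ld_rho = 0)
  ds <- co$dataset
  i1 <- which(ds$sample_table$pop == "pop1")
  ds1 <- subset_samples(ds, i1)
  y1 <- co$phenotype$pheno[i1]
  ss <- gwas_scan(ds1, y1)
  top <- ss$SNP[order(ss$p)[1:20]]
  out <- negative_control(ds1, y1, top, seed = 11)
  expect_lt(abs(out$rb - 1), 2 * out$se + 0.05)
})
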