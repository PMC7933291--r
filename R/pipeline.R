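# End-to-end synthetic reproductions of the three headline analyses:
# whole-genome bivariate GREML (per GRM mode, with/without PCs), stratified
# two-component GREML with the r_g difference test, and the summary-statistics
# sentinel-SNP r_b workflow with negative control.

#' Default pipeline configuration
#'
#' Desk-scale preset: 2,000 individuals per population, 5,000 SNPs, 1,000
#' causal, sized so the full pipeline runs in minutes on one core. All fields
#' can be overridden via `modifyList()`-style nested lists in [run_config()].
#'
#' @return A nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    simulate = list(n_pop1 = 2000L, n_pop2 = 2000L, m = 5000L,
                    m_causal = 1000L, fst_target = 0.1,
                    maf_range = c(0.1, 0.5), ld_block_size = 20L, ld_rho = 0.6,
                    rg_true = 0.75, h2_pop1 = 0.5, h2_pop2 = 0.4),
    grm = list(n_pcs = 20L),
    stratify = list(metric = "fst", n_freq_bins = 25L, n_ld_bins = 2L,
                    window_kb = 1000),
    sumstats = list(p_threshold = 1e-5, r2_threshold = 0.01, window_kb = 1000,
                    window2_kb = 10000, discovery_fraction = 0.5),
    seed = 1L), class = "run_config")
}

#' Build a pipeline configuration
#'
#' Starts from [default_config()] and applies nested overrides; unknown keys
#' are rejected.
#'
#' @param ... Named nested lists, e.g. `simulate = list(m = 1000)`.
#' @return A validated `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  for (section in names(over)) {
    if (!section %in% names(cfg)) stop("unknown config section: ", section)
    if (section == "seed") { cfg$seed <- over$seed; next }
    bad <- setdiff(names(over[[section]]), names(cfg[[section]]))
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in %s: %s", section,
                   paste(bad, collapse = ", ")))
    }
    cfg[[section]][names(over[[section]])] <- over[[section]]
  }
  cfg
}

sim_from_config <- function(config, seed) {
  s <- config$simulate
  model <- population_model(s$n_pop1, s$n_pop2, s$m, s$fst_target,
                            s$maf_range, s$ld_block_size, s$ld_rho)
  arch <- trait_architecture(s$m_causal, s$rg_true, s$h2_pop1, s$h2_pop2)
  simulate_cohort(model, arch, seed)
}

# Keep only SNPs polymorphic within both populations (needed by GRM-specific).
drop_population_monomorphic <- function(dataset) {
  pops <- dataset$sample_table$pop
  ok <- rep(TRUE, ncol(dataset$genotypes))
  for (k in unique(pops)) {
    p <- colMeans(dataset$genotypes[pops == k, , drop = FALSE], na.rm = TRUE) / 2
    ok <- ok & p > 0 & p < 1
  }
  if (all(ok)) dataset else subset_snps(dataset, which(ok))
}

#' Whole-genome bivariate GREML analogue
#'
#' Simulates a two-population cohort and estimates the cross-population
#' genetic correlation and per-population SNP heritabilities under both GRM
#' standardisation modes (population-specific and pooled frequencies), with
#' and without principal components as covariates, including the Wald test of
#' r_g = 1 and truth-vs-estimate deltas.
#'
#' @param config A `run_config`.
#' @param seed Optional override of `config$seed`.
#' @return List with `results` (one row per mode x PC setting), `truth`, and
#'   the fitted objects in `fits`.
#' @export
run_table1_analogue <- function(config = default_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  cohort <- sim_from_config(config, child_seed(seed, "table1_sim"))
  ds <- drop_population_monomorphic(cohort$dataset)
  y <- cohort$phenotype$pheno
  pop <- ds$sample_table$pop
  res <- list(); fits <- list()
  for (mode in c("specific", "average")) {
    grm <- compute_grm(ds, mode = mode)
    pcs <- compute_pcs(grm, config$grm$n_pcs)
    for (use_pcs in c(TRUE, FALSE)) {
      fit <- bivariate_greml(y, pop, grm,
                             covariates = if (use_pcs) pcs else NULL)
      wt <- if (is.finite(fit$rg$se[1]) && fit$rg$se[1] > 0) {
        wald_test(fit$rg$rg[1], fit$rg$se[1], null = 1)
      } else list(chisq = NA_real_, p = NA_real_)
      key <- sprintf("%s_%s", mode, if (use_pcs) "pcs" else "nopcs")
      fits[[key]] <- fit
      res[[key]] <- data.frame(
        mode = mode, pcs = use_pcs,
        rg = fit$rg$rg[1], rg_se = fit$rg$se[1], p_rg_eq_1 = wt$p,
        h2_pop1 = fit$h2$h2[1], h2_pop1_se = fit$h2$se[1],
        h2_pop2 = fit$h2$h2[2], h2_pop2_se = fit$h2$se[2],
        rg_minus_truth = fit$rg$rg[1] - config$simulate$rg_true,
        converged = fit$converged)
    }
  }
  list(results = do.call(rbind, c(res, make.row.names = FALSE)),
       truth = config$simulate[c("rg_true", "h2_pop1", "h2_pop2")],
       fits = fits)
}

#' Stratified r_g difference analogue
#'
#' Simulates a cohort, stratifies SNPs into low/high groups on FST (or LDCV)
#' within MAF/LD-matched bins, fits the two-component bivariate GREML, and
#' tests the difference in r_g between the strata. Balance diagnostics
#' (between-group differences of mean MAF and mean LD score, in SD units) are
#' always emitted.
#'
#' @inheritParams run_table1_analogue
#' @return List with `strata` (per-SNP table), `fit`, `test` (difference
#'   test), `balance` and `results` (one row per group).
#' @export
run_table2_analogue <- function(config = default_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  cohort <- sim_from_config(config, child_seed(seed, "table2_sim"))
  ds <- drop_population_monomorphic(cohort$dataset)
  y <- cohort$phenotype$pheno
  st <- snp_strata(ds, metric = config$stratify$metric,
                   n_freq_bins = config$stratify$n_freq_bins,
                   n_ld_bins = config$stratify$n_ld_bins,
                   window_kb = config$stratify$window_kb,
                   seed = child_seed(seed, "table2_split"))
  grm_all <- compute_grm(ds, mode = "specific")
  pcs <- compute_pcs(grm_all, config$grm$n_pcs)
  tc <- two_component_fit(ds, st$group, y, covariates = pcs)
  test <- rg_diff_test(tc$moments)
  balance <- strata_balance(st)
  res <- data.frame(group = c("low", "high"),
                    rg = c(test$rg1, test$rg2), se = c(test$se1, test$se2),
                    h2_pop1 = NA_real_, h2_pop2 = NA_real_)
  est <- tc$fit$estimates
  for (i in 1:2) {
    g <- c("low", "high")[i]
    res$h2_pop1[i] <- est[sprintf("Vg1_%s", g)] /
      (sum(est[sprintf("Vg1_%s", c("low", "high"))]) + est["Ve1"])
    res$h2_pop2[i] <- est[sprintf("Vg2_%s", g)] /
      (sum(est[sprintf("Vg2_%s", c("low", "high"))]) + est["Ve2"])
  }
  list(strata = st, fit = tc$fit, test = test, balance = balance,
       results = res)
}

#' Between-group balance diagnostics for a stratification
#'
#' Differences between the low and high groups in mean population-1 MAF, mean
#' population-2 frequency and mean LD score per population, expressed as a
#' fraction of each quantity's SD across SNPs.
#'
#' @param strata A per-SNP table from [snp_strata()].
#' @return Data frame with one row per diagnostic.
#' @export
strata_balance <- function(strata) {
  ok <- !is.na(strata$group)
  s <- strata[ok, ]
  metrics <- list(maf1 = pmin(s$freq1, 1 - s$freq1), freq2 = s$freq2,
                  ld1 = s$ld1, ld2 = s$ld2)
  rows <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    d <- mean(v[s$group == "high"]) - mean(v[s$group == "low"])
    data.frame(metric = nm, diff = d, sd = stats::sd(v),
               diff_over_sd = d / stats::sd(v))
  })
  do.call(rbind, rows)
}

#' Summary-statistics sentinel-SNP r_b analogue
#'
#' Splits population 1 into a discovery set and two disjoint estimation
#' subsets; scans the discovery set, clumps to sentinel SNPs (two rounds),
#' re-estimates effects in the first population-1 estimation subset and in
#' population 2, and computes the cross-population r_b, the same-population
#' negative control (between the two population-1 estimation subsets), and a
#' bivariate GREML restricted to the sentinel SNPs for comparison.
#'
#' @inheritParams run_table1_analogue
#' @return List with `sentinels`, `rb_cross`, `rb_control`, `rg_gws` (GREML at
#'   sentinels), `scatter` (per-sentinel effect table) and `results`.
#' @export
run_fig1_analogue <- function(config = default_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  cohort <- sim_from_config(config, child_seed(seed, "fig1_sim"))
  ds <- drop_population_monomorphic(cohort$dataset)
  y <- cohort$phenotype$pheno
  pops <- ds$sample_table$pop
  i1 <- which(pops == "pop1"); i2 <- which(pops == "pop2")
  n1 <- length(i1)
  split3 <- with_seed(child_seed(seed, "fig1_split"), {
    perm <- sample(i1)
    n_d <- round(n1 * config$sumstats$discovery_fraction)
    n_e <- floor((n1 - n_d) / 2)
    list(disc = sort(perm[seq_len(n_d)]),
         estA = sort(perm[n_d + seq_len(n_e)]),
         estB = sort(perm[(n_d + n_e + 1):n1]))
  })
  ds_disc <- subset_samples(ds, split3$disc)
  ss_disc <- gwas_scan(ds_disc, y[split3$disc])
  sen <- clump_two_round(ss_disc, ds_disc,
                         p_threshold = config$sumstats$p_threshold,
                         r2_threshold = config$sumstats$r2_threshold,
                         window_kb = config$sumstats$window_kb,
                         window2_kb = config$sumstats$window2_kb)
  if (length(sen$sentinels) < 10L) {
    stop(sprintf("only %d sentinel SNPs; increase sample size or relax p_threshold",
                 length(sen$sentinels)))
  }
  snp_idx <- sort(match(sen$sentinels, ds$snp_table$id))
  ss_estA <- gwas_scan(subset_samples(ds, split3$estA), y[split3$estA], snps = snp_idx)
  ss_estB <- gwas_scan(subset_samples(ds, split3$estB), y[split3$estB], snps = snp_idx)
  ss_pop2 <- gwas_scan(subset_samples(ds, i2), y[i2], snps = snp_idx)
  rb_cross <- rb_estimate(ss_estA, ss_pop2)
  rb_control <- rb_estimate(ss_estA, ss_estB)
  # bivariate GREML at the sentinel SNPs, estimation samples only
  est_samples <- c(split3$estA, i2)
  ds_est <- subset_samples(ds, est_samples)
  rg_gws <- tryCatch({
    grm_sen <- compute_grm(drop_population_monomorphic(
      subset_snps(ds_est, snp_idx)), mode = "specific")
    fit <- bivariate_greml(y[est_samples], pops[est_samples], grm_sen)
    list(rg = fit$rg$rg[1], se = fit$rg$se[1], fit = fit)
  }, error = function(e) list(rg = NA_real_, se = NA_real_, fit = NULL))
  list(sentinels = sen$sentinels,
       rb_cross = rb_cross, rb_control = rb_control, rg_gws = rg_gws,
       scatter = rb_cross$data,
       results = data.frame(
         quantity = c("rb_cross_population", "rb_negative_control",
                      "rg_greml_at_sentinels"),
         estimate = c(rb_cross$rb, rb_control$rb, rg_gws$rg),
         se = c(rb_cross$se, rb_control$se, rg_gws$se),
         k = c(rb_cross$k, rb_control$k, length(sen$sentinels))))
}
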