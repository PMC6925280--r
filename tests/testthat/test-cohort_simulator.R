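test_that("genotype simulation respects LD structure, HWE margins and seeds", {
  spec0 <- small_arch(K = 1, m = 40, block = 8L, r = 0, seed = 2)
  g0 <- simulate_genotypes(spec0, 5000)
  R <- cor(g0$dosages)
  off <- abs(R[upper.tri(R)])
  expect_lt(mean(off), 0.02)

  spec9 <- architecture_spec(
    40, rep(8L, 5), 0.9, maf_range = c(0.2, 0.5),
    traits = data.frame(label = "T", h2 = 0.3, causal_fraction = 0.5),
    seed = 2)
  g9 <- simulate_genotypes(spec9, 5000)
  within_r2 <- unlist(lapply(unique(spec9$block), function(b) {
    cols <- which(spec9$block == b)
    r2 <- cor(g9$dosages[, cols])^2
    r2[upper.tri(r2)]
  }))
  expect_gt(mean(within_r2), 0.5)

  # empirical allele frequency tracks the spec's MAF
  freq <- colMeans(g9$dosages) / 2
  expect_lt(max(abs(freq - spec9$maf)), 0.03)

  expect_identical(simulate_genotypes(spec9, 50, seed = 123)$dosages,
                   simulate_genotypes(spec9, 50, seed = 123)$dosages)

  expect_error(architecture_spec(10, c(5, 4), 0.5,
                                 traits = data.frame(label = "T", h2 = 0.3,
                                                     causal_fraction = 0.5)),
               class = "metagrs_validation_error")
  bad_corr <- matrix(c(1, 2, 2, 1), 2)
  expect_error(small_arch(K = 2, corr = 2),
               class = "metagrs_validation_error")
})

test_that("architecture effects follow the genetic correlation and h2", {
  # identity correlation: near-zero cross-trait effect correlation
  spec_id <- architecture_spec(
    10000, rep(10L, 1000), 0.4,
    traits = data.frame(label = c("A", "B"), h2 = 0.3,
                        causal_fraction = 1),
    genetic_corr = diag(2), seed = 5)
  eff_id <- simulate_architecture(spec_id)
  expect_lt(abs(cor(eff_id$effects[, 1], eff_id$effects[, 2])), 0.05)

  # strong correlation with a shared causal set
  spec_c <- architecture_spec(
    10000, rep(10L, 1000), 0.4,
    traits = data.frame(label = c("A", "B"), h2 = 0.3,
                        causal_fraction = 0.5),
    genetic_corr = matrix(c(1, 0.8, 0.8, 1), 2), seed = 6)
  eff_c <- simulate_architecture(spec_c)
  shared <- eff_c$causal[, 1] & eff_c$causal[, 2]
  r <- cor(eff_c$effects[shared, 1], eff_c$effects[shared, 2])
  expect_gt(r, 0.7)
  expect_lt(r, 0.9)

  # h2 = 0 trait: all effects exactly zero
  spec_0 <- architecture_spec(
    100, rep(10L, 10), 0.4,
    traits = data.frame(label = c("A", "Z"), h2 = c(0.3, 0),
                        causal_fraction = 0.5), seed = 7)
  eff_0 <- simulate_architecture(spec_0)
  expect_true(all(eff_0$effects[, "Z"] == 0))
  # non-causal entries are exact zeros
  expect_true(all(eff_0$effects[!eff_0$causal[, "A"], "A"] == 0))
})

test_that("realized heritability matches the specification", {
  spec <- architecture_spec(
    2000, rep(10L, 200), 0.5,
    traits = data.frame(label = c("A", "B"), h2 = c(0.25, 0.4),
                        causal_fraction = 0.5), seed = 9)
  g <- simulate_genotypes(spec, 8000, seed = 99)
  eff <- simulate_architecture(spec)
  gv <- g$dosages %*% eff$effects
  for (k in 1:2) {
    h2_real <- var(gv[, k]) / (var(gv[, k]) + (1 - spec$traits$h2[k]))
    expect_lt(abs(h2_real - spec$traits$h2[k]), 0.02)
  }
})

test_that("summary statistics concentrate with GWAS sample size", {
  spec <- small_arch(K = 2, m = 200, block = 10L, seed = 31)
  eff <- simulate_architecture(spec)

  huge <- simulate_sumstats(eff, spec, gwas_n = 1e9)
  expect_lt(max(abs(huge[[1]]$beta - eff$effects[, 1])), 1e-3)

  # a null trait yields uniform p-values
  spec_null <- architecture_spec(
    10000, rep(10L, 1000), 0,
    traits = data.frame(label = "N", h2 = 0, causal_fraction = 0.5),
    seed = 12)
  eff_null <- simulate_architecture(spec_null)
  ss_null <- simulate_sumstats(eff_null, spec_null, gwas_n = 10000)
  expect_gt(stats::ks.test(ss_null[[1]]$pvalue, "punif")$p.value, 0.01)

  # doubling n shrinks the median absolute error by about sqrt(2)
  s1 <- simulate_sumstats(eff, spec, gwas_n = 10000,
                          seed = derive_seed(1, "a"))
  s2 <- simulate_sumstats(eff, spec, gwas_n = 20000,
                          seed = derive_seed(1, "b"))
  ratio <- median(abs(s1[[1]]$beta - eff$effects[, 1])) /
    median(abs(s2[[1]]$beta - eff$effects[, 1]))
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.7)

  expect_error(simulate_sumstats(eff, spec, gwas_n = 50),
               class = "metagrs_validation_error")
})

test_that("risk-factor derivation applies the medication and threshold rules", {
  df <- data.frame(sbp = c(130, 141, 120, 139),
                   dbp = c(80, 80, 91, 85),
                   ldl = c(3, 4, 5, 2),
                   bp_med = c(1, 0, 0, 0),
                   lipid_med = c(0, 1, 0, 0),
                   hypertension_record = c(0, 0, 0, 1))
  out <- derive_risk_factors(df)
  expect_equal(out$sbp_adjusted, c(145, 141, 120, 139))
  expect_equal(out$ldl_adjusted, c(3, 5.5, 5, 2))
  # med | SBP > 140 | DBP > 90 | record
  expect_equal(out$hypertension, c(1, 1, 1, 1))
  out2 <- derive_risk_factors(transform(df, bp_med = 0,
                                        hypertension_record = 0))
  expect_equal(out2$hypertension, c(0, 1, 1, 0))

  expect_error(derive_risk_factors(transform(df, bp_med = NA)),
               class = "metagrs_validation_error")
})

test_that("survival simulation truncates, censors and stores truth", {
  n <- 20000
  set.seed(3)
  df <- data.frame(sample_id = sprintf("i%05d", 1:n), liab = rnorm(n))

  # null effect: event ages unrelated to the predictor
  s0 <- simulate_survival(df, c(liab = 0), baseline_rate = 2e-4,
                          followup_years = 15, seed = 5)
  ev <- s0$records[s0$records$event == 1, ]
  expect_gt(nrow(ev), 100)
  expect_lt(abs(cor(ev$exit_age, ev$liab, method = "spearman")), 0.05)

  # administrative cap honoured; prevalent cases excluded and flagged
  s1 <- simulate_survival(df, c(liab = log(1.26)), baseline_rate = 2e-4,
                          followup_years = 40, admin_cap = 75, seed = 6)
  expect_lte(max(s1$records$exit_age), 75)
  expect_true(all(s1$records$exit_age > s1$records$entry_age))
  expect_true(all(s1$prevalent$event_age <= s1$prevalent$entry_age))
  expect_equal(nrow(s1$records) + nrow(s1$prevalent), n)
  expect_equal(s1$truth$loghr[["liab"]], log(1.26))

  expect_error(simulate_survival(df, c(liab = 0.1), baseline_rate = 0),
               class = "metagrs_validation_error")
  expect_error(simulate_survival(df, c(missing_col = 0.1)),
               class = "metagrs_format_error")
})

test_that("oversampled splits enrich cases and carry inverse-probability weights", {
  n <- 100000
  set.seed(14)
  rec <- survival_records(data.frame(
    sample_id = sprintf("s%06d", 1:n),
    entry_age = runif(n, 40, 69), exit_age = 74.9,
    event = rbinom(n, 1, 0.01)))
  rec$exit_age <- rec$entry_age + runif(n, 1, 5)

  # factor 1: simple random split, all weights equal
  sp1 <- split_oversampled(rec, split_spec(10000, 1, seed = 4))
  expect_equal(length(unique(sp1$validation$weight)), 1L)
  expect_equal(nrow(sp1$derivation) + nrow(sp1$validation), n)
  expect_equal(length(intersect(sp1$derivation$sample_id,
                                sp1$validation$sample_id)), 0L)

  # factor 10 at 1% prevalence: derivation case fraction near 9-10%
  sp10 <- split_oversampled(rec, split_spec(10000, 10, seed = 4))
  frac <- mean(sp10$derivation$event)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.11)
  expect_equal(nrow(sp10$derivation), 10000, tolerance = 0.05)
  # validation weights: cases retained with lower probability get larger
  # weights
  wc <- unique(sp10$validation$weight[sp10$validation$event == 1])
  w0 <- unique(sp10$validation$weight[sp10$validation$event == 0])
  expect_gt(wc, w0)

  expect_error(split_oversampled(rec, split_spec(90000, 50)),
               class = "metagrs_validation_error")
})

test_that("the full simulated cohort is reproducible and structurally sound", {
  spec <- small_arch(K = 2, m = 40, block = 8L, seed = 44)
  c1 <- simulate_cohort(spec, 800, gwas_n = 20000, baseline_rate = 2e-5)
  c2 <- simulate_cohort(spec, 800, gwas_n = 20000, baseline_rate = 2e-5)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$records$exit_age, c2$records$exit_age)
  expect_identical(c1$sumstats[[1]]$beta, c2$sumstats[[1]]$beta)

  expect_equal(ncol(c1$liability), 2L)
  expect_true(all(c1$factors$hypertension %in% 0:1))
  expect_true(all(c1$records$stratum %in% c("female", "male")))
  # SBP adjustment reconstructs the underlying treated value
  f <- derive_risk_factors(c1$factors)
  treated <- f$bp_med == 1
  expect_equal(f$sbp_adjusted[treated], f$sbp[treated] + 15)
})
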