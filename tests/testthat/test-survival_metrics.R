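test_that("Cox fits recover null, true, and weight-invariant effects", {
  null_sim <- sim_score_cohort(4000, 0, seed = 101)
  rec <- null_sim$records
  rec$noise <- rnorm(nrow(rec))
  f0 <- fit_cox(rec, "noise")
  expect_lt(abs(f0$beta[["noise"]]), 2 * f0$robust_se[["noise"]])

  # parameter recovery at HR 1.26 per SD
  sim <- sim_score_cohort(50000, log(1.26), seed = 707)
  f1 <- fit_cox(sim$records, "score")
  hr <- hr_per_sd(f1, "score")
  expect_gt(hr[["hr"]], 1.20)
  expect_lt(hr[["hr"]], 1.32)

  # common weight scaling leaves the estimate unchanged
  rec2 <- sim$records
  rec2$weight <- 2
  f2 <- fit_cox(rec2, "score")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)

  # baseline cumulative hazard is a non-decreasing step function from 0
  bl <- f1$baseline_cumhaz
  for (s in unique(bl$stratum)) {
    h <- bl$cumhaz[bl$stratum == s]
    expect_true(all(diff(h) >= 0))
    expect_gte(min(h), 0)
  }

  no_event <- sim$records[sim$records$event == 0, ][1:50, ]
  expect_error(fit_cox(no_event, "score"),
               class = "metagrs_degenerate_fit_error")
})

test_that("hazard-ratio helpers apply the closed forms", {
  fake <- structure(list(beta = c(x = 0), robust_se = c(x = 0.1)),
                    class = "cox_result")
  expect_equal(hr_per_sd(fake, "x")[["hr"]], 1.0)
  fake2 <- structure(list(beta = c(x = log(2)), robust_se = c(x = 0)),
                     class = "cox_result")
  expect_equal(unname(hr_per_sd(fake2, "x")), c(2, 2, 2))
  expect_error(hr_per_sd(fake, "y"), class = "metagrs_validation_error")
})

test_that("CI for HR per SD covers truth at roughly nominal rate", {
  covered <- 0L
  for (seed in 1:20) {
    sim <- sim_score_cohort(12000, log(1.26), seed = 3000 + seed)
    ci <- hr_per_sd(fit_cox(sim$records, "score"), "score")
    if (ci[["lower"]] <= 1.26 && 1.26 <= ci[["upper"]]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 17L)
})

test_that("percentile-bin hazard ratios behave under null and signal", {
  set.seed(55)
  null_sim <- sim_score_cohort(6000, 0, seed = 11)
  rec <- null_sim$records
  sv <- score_vector(rec$sample_id, rnorm(nrow(rec)))
  bins <- percentile_bins(c(0, 0.1, 0.45, 0.55, 0.9, 1))
  out <- percentile_bin_hr(sv, rec, bins)
  non_ref <- out[!out$reference, ]
  expect_true(all(non_ref$lower < 1 & non_ref$upper > 1))

  # monotone risk: top bin HR > 1 > bottom bin HR
  b <- log(1.5)
  sim <- sim_score_cohort(30000, b, seed = 21)
  rec2 <- sim$records
  sv2 <- score_vector(rec2$sample_id, rec2$score)
  out2 <- percentile_bin_hr(sv2, rec2,
                            percentile_bins(c(0, 0.1, 0.45, 0.55, 0.95, 1)))
  expect_gt(out2$hr[out2$bin == "95-100%"], 1)
  expect_lt(out2$hr[out2$bin == "0-10%"], 1)

  # truncated-normal oracle: top-bin log HR ~ b * (E[Z | top] - E[Z | mid])
  delta <- dnorm(qnorm(0.95)) / 0.05 - 0  # reference bin mean ~ 0
  expected <- b * delta
  got <- log(out2$hr[out2$bin == "95-100%"])
  expect_lt(abs(got - expected), 0.35)

  expect_error(percentile_bins(c(0, 0.5, 0.4, 1)),
               class = "metagrs_validation_error")
  expect_error(percentile_bins(c(0, 0.5, 1), reference = c(0.45, 0.55)),
               class = "metagrs_validation_error")
})

test_that("Harrell's C matches the exhaustive pair oracle", {
  # worked fixture: exit 2,4,5,7,9; events 1,1,0,1,0; scores 5,4,3,2,1
  rec <- survival_records(data.frame(
    sample_id = letters[1:5], entry_age = 40,
    exit_age = 40 + c(2, 4, 5, 7, 9), event = c(1, 1, 0, 1, 0)))
  sc <- c(5, 4, 3, 2, 1)
  res <- harrell_c(rec, sc)
  oracle <- cindex_oracle(rec$entry_age, rec$exit_age, rec$event, sc)
  expect_equal(res[["c"]], oracle$c)
  expect_equal(res[["c"]], 1)

  # random left-truncated fixtures with score ties
  for (seed in 1:15) {
    set.seed(seed)
    n <- 30
    entry <- runif(n, 40, 60)
    rec2 <- survival_records(data.frame(
      sample_id = sprintf("x%02d", 1:n), entry_age = entry,
      exit_age = entry + runif(n, 0.5, 12), event = rbinom(n, 1, 0.6)))
    sc2 <- sample(1:8, n, replace = TRUE)  # induces ties
    expect_equal(harrell_c(rec2, sc2)[["c"]],
                 cindex_oracle(rec2$entry_age, rec2$exit_age, rec2$event,
                               sc2)$c,
                 tolerance = 1e-12)
  }

  # random score: CI covers 0.5
  sim <- sim_score_cohort(5000, 0, seed = 77)
  rnd <- rnorm(nrow(sim$records))
  cc <- harrell_c(sim$records, rnd)
  expect_true(cc[["lower"]] < 0.5 && 0.5 < cc[["upper"]])

  expect_error(harrell_c(rec[rec$event == 0, ], sc[c(3, 5)]),
               class = "metagrs_validation_error")
})

test_that("Kaplan-Meier handles delayed entry; log-rank is calibrated and powered", {
  # no events: survival identically 1
  rec <- survival_records(data.frame(
    sample_id = letters[1:4], entry_age = 41:44,
    exit_age = 51:54, event = 0))
  km <- kaplan_meier(rec, rep("a", 4))
  expect_true(all(km$curves$surv == 1))

  # matches survdiff chi-square on right-censored data (entry at ~0)
  set.seed(9)
  n <- 300
  df <- data.frame(time = rexp(n, 0.1), ev = rbinom(n, 1, 0.7),
                   g = sample(c("A", "B"), n, TRUE))
  rec2 <- survival_records(data.frame(
    sample_id = as.character(1:n), entry_age = 1e-7, exit_age = df$time,
    event = df$ev), admin_cap = Inf)
  km2 <- kaplan_meier(rec2, df$g)
  sd2 <- survival::survdiff(survival::Surv(time, ev) ~ g, data = df)
  expect_equal(km2$logrank_chisq, sd2$chisq, tolerance = 1e-8)

  # null calibration: p-values uniform over 200 seeded replicates
  pvals <- vapply(1:200, function(seed) {
    sim <- sim_score_cohort(400, 0, seed = 5000 + seed,
                            baseline_rate = 2e-4)
    g <- rep_len(c("g1", "g2"), nrow(sim$records))
    kaplan_meier(sim$records, g)$logrank_p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # power: simulated HR 2 between groups, n = 2000 per group
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    grp <- rep(c(0, 1), each = 2000)
    df3 <- data.frame(sample_id = as.character(1:4000), x = grp)
    sim3 <- simulate_survival(df3, c(x = log(2) * sd(grp) / 1),
                              baseline_rate = 2e-5, followup_years = 15,
                              seed = 900 + seed)
    # per-SD scaling: convert so the group contrast is log(2)
    rec3 <- sim3$records
    if (kaplan_meier(rec3, rec3$x)$logrank_p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  expect_error(kaplan_meier(rec, factor(rep("a", 4), levels = c("a", "b"))),
               class = "metagrs_validation_error")
})

test_that("predicted cumulative incidence follows the baseline-hazard formula", {
  sim <- sim_score_cohort(8000, log(1.3), seed = 31)
  rec <- sim$records
  fit <- fit_cox(rec, "score")

  grid <- c(55, 60, 65, 70)
  ci <- cumulative_incidence(fit, data.frame(score = 0), grid)
  # at x'beta = 0 the curve equals 1 - exp(-H0(t)) with H0 centred at 0
  sf <- survival::survfit(fit$fit, newdata = data.frame(score = 0),
                          ctype = 1)
  idx <- findInterval(grid, sf$time)
  manual <- 1 - exp(-ifelse(idx == 0, 0, sf$cumhaz[pmax(idx, 1)]))
  expect_equal(ci$risk, manual, tolerance = 1e-12)

  # before the first at-risk age the risk is zero
  early <- cumulative_incidence(fit, data.frame(score = 0), 30)
  expect_equal(early$risk, 0)

  # monotone in t and in the linear predictor
  expect_true(all(diff(ci$risk) >= 0))
  ci_hi <- cumulative_incidence(fit, data.frame(score = 2), grid)
  expect_true(all(ci_hi$risk >= ci$risk))

  expect_warning(cumulative_incidence(fit, data.frame(score = 0), 76),
                 "flat")
})

test_that("decile calibration honours the odds-scale rescaling contract", {
  # halving odds: a small prediction is roughly halved
  out <- calibration_by_decile(rep(c(0.01, 0.2), 60),
                               rbinom(120, 1, 0.1), rate_ratio = 2)
  small <- min(out$mean_predicted)
  expect_equal(small, (0.01 / 0.99 / 2) / (1 + 0.01 / 0.99 / 2),
               tolerance = 1e-12)

  # identical predictions collapse to a single bin
  set.seed(8)
  y <- rbinom(400, 1, 0.3)
  one <- calibration_by_decile(rep(0.3, 400), y)
  expect_equal(nrow(one), 1L)
  expect_equal(one$observed, mean(y))

  # rescaling by the derivation/validation rate ratio restores the mean
  # event rate on the prediction scale (self-calibration itself is
  # exercised in the acceptance suite)
  set.seed(12)
  p <- plogis(rnorm(20000, -2, 1))
  yy <- rbinom(length(p), 1, p)
  cal <- calibration_by_decile(p, yy, rate_ratio = 1)
  expect_equal(sum(cal$n), length(p))
  expect_equal(sum(cal$n_event), sum(yy))
  expect_true(all(diff(cal$mean_predicted) > 0))

  expect_error(calibration_by_decile(p, yy, rate_ratio = 0),
               class = "metagrs_validation_error")
  expect_error(calibration_by_decile(c(0, 0.5), c(0, 1)),
               class = "metagrs_validation_error")
})

test_that("interaction Wald tests are calibrated, powered, and guarded", {
  # null: uniform p over 200 replicates (cox model)
  pvals <- vapply(1:200, function(seed) {
    set.seed(7000 + seed)
    n <- 400
    df <- data.frame(sample_id = as.character(1:n), a = rnorm(n),
                     b = rnorm(n))
    sim <- simulate_survival(df, c(a = 0.3, b = 0.2),
                             baseline_rate = 2e-4, followup_years = 15,
                             seed = 7000 + seed)
    test_interaction(sim$records, "a", "b")$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # power: strong product effect detected
  hits <- 0L
  for (seed in 1:20) {
    set.seed(8000 + seed)
    n <- 20000
    df <- data.frame(sample_id = as.character(1:n), a = rnorm(n),
                     b = rnorm(n))
    df$ab <- df$a * df$b
    sim <- simulate_survival(df, c(a = 0.1, b = 0.1, ab = 0.5),
                             baseline_rate = 2e-5, followup_years = 15,
                             seed = 8000 + seed)
    if (test_interaction(sim$records, "a", "b")$p < 0.01) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)

  sim <- sim_score_cohort(500, 0, seed = 1)
  rec <- sim$records
  rec$const <- 1
  expect_error(test_interaction(rec, "score", "const"),
               class = "metagrs_validation_error")

  # logistic route returns a Wald p for the product term
  rec$b2 <- rnorm(nrow(rec))
  lt <- test_interaction(rec, "score", "b2", model = "logistic")
  expect_true(is.finite(lt$p) && lt$p >= 0 && lt$p <= 1)
})

test_that("liability-scale conversion matches closed forms and a numeric oracle", {
  expect_equal(r2_to_liability(0, liability_params(0.1, 0.3)), 0)

  # P = K = 0.5: factor 0.25 / dnorm(0)^2
  f <- liability_factor(0.5, 0.5)
  expect_equal(f, 0.25 / dnorm(0)^2, tolerance = 1e-12)
  expect_equal(r2_to_liability(0.01, liability_params(0.5, 0.5)),
               0.01 * f)

  # P = K limit equals the classic single factor K(1-K)/z^2 exactly
  for (K in c(0.008, 0.05, 0.2)) {
    z <- dnorm(qnorm(1 - K))
    expect_equal(liability_factor(K, K), K * (1 - K) / z^2,
                 tolerance = 1e-12)
    # ascertainment-corrected method reduces to linear at P = K
    expect_equal(r2_to_liability(0.02, liability_params(K, K),
                                 method = "corrected"),
                 r2_to_liability(0.02, liability_params(K, K)),
                 tolerance = 1e-12)
  }

  # numeric threshold-model oracle at K = 0.008, P = 0.074:
  # threshold and density recovered by integration of the normal density
  K <- 0.008; P <- 0.074
  thr <- uniroot(function(t) integrate(dnorm, t, Inf)$value - K,
                 c(0, 6), tol = 1e-12)$root
  z_num <- dnorm(thr)
  oracle <- K * (1 - K) / z_num^2 * K * (1 - K) / (P * (1 - P))
  expect_equal(liability_factor(K, P), oracle, tolerance = 1e-6)

  expect_error(liability_params(0, 0.1),
               class = "metagrs_validation_error")
})

test_that("explained heritability scales inversely with h2", {
  expect_equal(unname(explained_heritability(0, c(0.1, 0.4))), c(0, 0))
  eh <- explained_heritability(0.008, c(0.1, 0.4))
  expect_equal(unname(eh[1]), 0.08)
  expect_equal(unname(eh[1] / eh[2]), 4.0)
  expect_true(all(diff(explained_heritability(0.01,
                                              seq(0.1, 0.4, 0.1))) < 0))
  expect_error(explained_heritability(0.01, c(0, 0.1)),
               class = "metagrs_validation_error")
})
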