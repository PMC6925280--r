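#' Specification of a simulated genetic architecture
#'
#' Defines the variant panel (LD blocks, allele frequencies) and the
#' correlated multi-trait architecture from which genotypes, effect sizes
#' and summary statistics are generated. Variant metadata (positions,
#' alleles, allele frequencies) is drawn once, at construction, from
#' `seed`, so every generator sees the same panel.
#'
#' @param n_variants Total number of variants.
#' @param block_sizes Variants per LD block; must sum to `n_variants`.
#' @param within_block_r Exchangeable latent correlation within a block,
#'   in \[0, 1).
#' @param maf_range `(low, high)` range of minor-allele frequencies, a
#'   subset of (0, 0.5\].
#' @param traits Data frame with `label`, `h2` (liability heritability in
#'   \[0, 1)) and `causal_fraction` in (0, 1\].
#' @param genetic_corr K x K symmetric positive-semidefinite genetic
#'   correlation matrix with unit diagonal (default identity).
#' @param seed Integer master seed.
#' @return An `architecture_spec` with the variant table and per-variant
#'   allele frequencies attached.
#' @export
architecture_spec <- function(n_variants, block_sizes, within_block_r,
                              maf_range = c(0.05, 0.5), traits,
                              genetic_corr = NULL, seed = 1L) {
  if (sum(block_sizes) != n_variants) {
    stop_validation("block_sizes must sum to n_variants")
  }
  assert_number(within_block_r, "within_block_r", 0, 1, open_upper = TRUE)
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L]) {
    stop_validation("maf_range must be an increasing pair inside (0, 0.5]")
  }
  assert_columns(traits, c("label", "h2", "causal_fraction"), "traits")
  if (any(traits$h2 < 0 | traits$h2 >= 1)) {
    stop_validation("trait h2 must lie in [0, 1)")
  }
  if (any(traits$causal_fraction <= 0 | traits$causal_fraction > 1)) {
    stop_validation("causal_fraction must lie in (0, 1]")
  }
  if (any(ceiling(traits$causal_fraction * n_variants) < 1)) {
    stop_validation("causal_fraction x n_variants must be >= 1")
  }
  K <- nrow(traits)
  if (is.null(genetic_corr)) genetic_corr <- diag(K)
  genetic_corr <- as.matrix(genetic_corr)
  if (!isSymmetric(genetic_corr) ||
      any(abs(diag(genetic_corr) - 1) > 1e-8)) {
    stop_validation("genetic_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_validation("genetic_corr must be positive semi-definite")
  }

  # variant panel drawn once: 1 kb spacing within a block, 1 Mb gaps
  # between blocks, non-strand-ambiguous allele pairs
  panel <- with_seed(derive_seed(seed, "panel"), {
    maf <- runif(n_variants, maf_range[1L], maf_range[2L])
    block <- rep(seq_along(block_sizes), block_sizes)
    offset <- c(0, cumsum(block_sizes[-length(block_sizes)]))
    within <- sequence(block_sizes)
    pos <- offset[block] * 1000L + (block - 1L) * 1000000L + within * 1000L
    pair <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                   byrow = TRUE)
    pick <- sample.int(4L, n_variants, replace = TRUE)
    list(variants = data.frame(
      chrom = "1", pos = as.integer(pos),
      id = sprintf("rs%06d", seq_len(n_variants)),
      effect_allele = pair[pick, 1L], other_allele = pair[pick, 2L],
      stringsAsFactors = FALSE),
      maf = maf, block = block)
  })

  structure(list(n_variants = n_variants, block_sizes = block_sizes,
                 within_block_r = within_block_r, maf_range = maf_range,
                 traits = as.data.frame(traits, stringsAsFactors = FALSE),
                 genetic_corr = genetic_corr, seed = as.integer(seed),
                 variants = panel$variants, maf = panel$maf,
                 block = panel$block),
            class = "architecture_spec")
}

#' Simulate LD-blocked hard-call genotypes
#'
#' Draws a latent standard-normal value per sample and variant with
#' exchangeable correlation `within_block_r` inside each LD block, and
#' discretises it to dosages \{0, 1, 2\} at the Hardy-Weinberg thresholds
#' of each variant's allele frequency (`P(0) = (1-maf)^2`,
#' `P(2) = maf^2`).
#'
#' @param spec An [architecture_spec()].
#' @param n_samples Number of samples.
#' @param seed Seed (default derived from the spec seed).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(spec, n_samples,
                               seed = derive_seed(spec$seed, "genotypes")) {
  r <- spec$within_block_r
  with_seed(seed, {
    dos <- matrix(0L, n_samples, spec$n_variants)
    for (b in unique(spec$block)) {
      cols <- which(spec$block == b)
      shared <- rnorm(n_samples)
      Z <- sqrt(r) * shared +
        sqrt(1 - r) * matrix(rnorm(n_samples * length(cols)), n_samples)
      maf <- spec$maf[cols]
      q0 <- qnorm((1 - maf)^2)
      q2 <- qnorm(1 - maf^2)
      dos[, cols] <- (sweep(Z, 2L, q0, ">")) + (sweep(Z, 2L, q2, ">"))
    }
    genotype_matrix(sprintf("S%06d", seq_len(n_samples)), spec$variants,
                    dos)
  })
}

#' Simulate per-trait true effect-size vectors
#'
#' Causal sets are nested across traits (a master permutation is truncated
#' at each trait's causal fraction), so traits share causal variants and
#' the cross-trait correlation of effects at shared variants follows
#' `genetic_corr` (Cholesky construction). Effects are scaled so that the
#' genetic variance of each trait's dosage score equals its `h2` (scaling
#' uses an internal seeded reference panel so the realised heritability
#' includes LD).
#'
#' @param spec An [architecture_spec()].
#' @param seed Seed (default derived from the spec seed).
#' @param n_ref Size of the internal reference panel used to scale
#'   genetic variances (default 2000).
#' @return List with `effects` (variants x traits matrix, exact zeros for
#'   non-causal entries), `causal` (logical matrix), and `maf`.
#' @export
simulate_architecture <- function(spec,
                                  seed = derive_seed(spec$seed, "effects"),
                                  n_ref = 2000L) {
  m <- spec$n_variants
  K <- nrow(spec$traits)
  with_seed(seed, {
    perm <- sample.int(m)
    L <- chol(spec$genetic_corr + diag(1e-10, K))
    B <- matrix(rnorm(m * K), m, K) %*% L
    causal <- matrix(FALSE, m, K)
    for (k in seq_len(K)) {
      n_causal <- ceiling(spec$traits$causal_fraction[k] * m)
      causal[perm[seq_len(n_causal)], k] <- TRUE
    }
    B[!causal] <- 0
    ref <- simulate_genotypes(spec, n_ref,
                              seed = derive_seed(spec$seed, "scaling-panel"))
    G <- ref$dosages %*% B
    for (k in seq_len(K)) {
      h2 <- spec$traits$h2[k]
      if (h2 == 0) {
        B[, k] <- 0
        causal[, k] <- FALSE
        next
      }
      v <- var(G[, k])
      B[, k] <- B[, k] * sqrt(h2 / v)
    }
    colnames(B) <- spec$traits$label
    colnames(causal) <- spec$traits$label
    list(effects = B, causal = causal, maf = spec$maf)
  })
}

#' Simulate external-GWAS summary statistics
#'
#' Adds sampling noise to the true per-allele effects with standard error
#' `1 / sqrt(2 n maf (1 - maf))` and computes Wald p-values. The noise is
#' independent of any simulated target cohort (no sample overlap).
#'
#' @param effects Output of [simulate_architecture()].
#' @param spec The [architecture_spec()].
#' @param gwas_n Named (by trait) or unnamed vector of GWAS sample sizes
#'   (each >= 100), recycled over traits.
#' @param seed Seed (default derived from the spec seed).
#' @return Named list of `sumstats` tables, one per trait.
#' @export
simulate_sumstats <- function(effects, spec, gwas_n,
                              seed = derive_seed(spec$seed, "sumstats")) {
  labels <- colnames(effects$effects)
  gwas_n <- rep_len(gwas_n, length(labels))
  if (any(gwas_n < 100)) stop_validation("gwas_n must be >= 100")
  maf <- spec$maf
  with_seed(seed, {
    out <- lapply(seq_along(labels), function(k) {
      se <- 1 / sqrt(2 * gwas_n[k] * maf * (1 - maf))
      alpha_hat <- effects$effects[, k] + rnorm(length(maf)) * se
      tab <- spec$variants
      tab$beta <- alpha_hat
      tab$se <- se
      tab$pvalue <- 2 * pnorm(-abs(alpha_hat / se))
      tab$eaf <- maf
      tab$info <- runif(length(maf), 0.3, 1)
      new_sumstats(tab, labels[k])
    })
    names(out) <- labels
    out
  })
}

#' Apply the risk-factor derivation rules
#'
#' Reconstructs underlying blood pressure and LDL for treated individuals
#' and applies the expanded hypertension definition: `sbp_adjusted = sbp +
#' 15` mm Hg when on BP medication, `ldl_adjusted = ldl + 1.5` mmol/L when
#' on lipid-lowering medication, and `hypertension = bp_med | sbp > 140 |
#' dbp > 90 | record flag`.
#'
#' @param factors Data frame with `sbp`, `dbp`, `ldl`, `bp_med`,
#'   `lipid_med` and optionally `hypertension_record` (0/1 registry flag,
#'   assumed 0 when absent).
#' @return The data frame with `sbp_adjusted`, `ldl_adjusted` and
#'   `hypertension` columns added.
#' @export
derive_risk_factors <- function(factors) {
  assert_columns(factors, c("sbp", "dbp", "ldl", "bp_med", "lipid_med"),
                 "risk factors")
  if (anyNA(factors$bp_med) || anyNA(factors$lipid_med)) {
    stop_validation("medication flags must be complete")
  }
  rec <- if ("hypertension_record" %in% names(factors)) {
    factors$hypertension_record
  } else 0
  factors$sbp_adjusted <- factors$sbp + 15 * (factors$bp_med == 1)
  factors$ldl_adjusted <- factors$ldl + 1.5 * (factors$lipid_med == 1)
  factors$hypertension <- as.integer(
    factors$bp_med == 1 | factors$sbp > 140 | factors$dbp > 90 | rec == 1)
  factors
}

#' Simulate left-truncated, age-censored survival records
#'
#' Event ages are drawn from a Gompertz proportional-hazards model
#' `h(t) = rate * rr_stratum * exp(shape * t + lp)` with the linear
#' predictor `lp = sum_v loghr[v] * standardise(data[[v]])` (per-SD log
#' hazard ratios). Entry ages are drawn uniformly when absent. Events at
#' or before entry are prevalent: they are excluded from the incident
#' records and returned in a flagged registry. Exits are censored at
#' `entry + followup_years` and administratively at `admin_cap`.
#'
#' @param data Data frame with `sample_id`, the predictor columns named in
#'   `loghr`, optionally `stratum` and `entry_age`.
#' @param loghr Named numeric vector of per-SD log hazard ratios.
#' @param baseline_shape,baseline_rate Gompertz shape (per year) and rate
#'   (per year, reference stratum) — both > 0.
#' @param stratum_rate_ratio Named baseline-rate multipliers per stratum
#'   (default 1 for every stratum).
#' @param entry_age_range Uniform entry-age range used when `data` lacks
#'   `entry_age`.
#' @param followup_years Censoring horizon after entry.
#' @param admin_cap Administrative censoring age (default 75).
#' @param seed Optional seed.
#' @return List with `records` (incident [survival_records()], including
#'   the predictor columns and true `lp`), `prevalent` (data frame of
#'   excluded prevalent cases), and `truth` (the generating parameters).
#' @export
simulate_survival <- function(data, loghr, baseline_shape = 0.09,
                              baseline_rate = 2e-6,
                              stratum_rate_ratio = NULL,
                              entry_age_range = c(40, 69),
                              followup_years = 7, admin_cap = 75,
                              seed = NULL) {
  assert_number(baseline_shape, "baseline_shape", 0, Inf, open_lower = TRUE)
  assert_number(baseline_rate, "baseline_rate", 0, Inf, open_lower = TRUE)
  assert_columns(data, c("sample_id", names(loghr)), "data")
  n <- nrow(data)
  if (!"stratum" %in% names(data)) data$stratum <- "all"
  with_seed(seed, {
    if (!"entry_age" %in% names(data)) {
      data$entry_age <- runif(n, entry_age_range[1L], entry_age_range[2L])
    }
    lp <- rep(0, n)
    for (v in names(loghr)) {
      x <- as.numeric(data[[v]])
      sdx <- sd(x)
      if (sdx == 0) stop_validation("predictor `%s` is constant", v)
      lp <- lp + loghr[[v]] * (x - mean(x)) / sdx
    }
    rr <- if (is.null(stratum_rate_ratio)) {
      rep(1, n)
    } else {
      unname(stratum_rate_ratio[as.character(data$stratum)])
    }
    if (anyNA(rr)) stop_validation("stratum_rate_ratio lacks some strata")
    rate_i <- baseline_rate * rr * exp(lp)
    u <- runif(n)
    event_age <- log1p(baseline_shape * (-log(u)) / rate_i) / baseline_shape

    prevalent <- event_age <= data$entry_age
    censor_age <- pmin(data$entry_age + followup_years, admin_cap)
    exit_age <- pmin(event_age, censor_age)
    event <- as.integer(event_age <= censor_age)

    inc <- data[!prevalent, , drop = FALSE]
    inc$exit_age <- exit_age[!prevalent]
    inc$event <- event[!prevalent]
    inc$lp <- lp[!prevalent]
    records <- survival_records(inc, admin_cap = admin_cap)
    prev <- data.frame(sample_id = data$sample_id[prevalent],
                       event_age = event_age[prevalent],
                       entry_age = data$entry_age[prevalent],
                       prevalent = TRUE, stringsAsFactors = FALSE)
    list(records = records, prevalent = prev,
         truth = list(loghr = loghr, baseline_shape = baseline_shape,
                      baseline_rate = baseline_rate,
                      stratum_rate_ratio = stratum_rate_ratio,
                      admin_cap = admin_cap,
                      followup_years = followup_years))
  })
}

#' Derivation/validation split specification
#'
#' @param derivation_n Expected derivation-set size.
#' @param case_oversample_factor Cases enter the derivation set with this
#'   multiple of the control selection probability (>= 1).
#' @param seed Integer seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(derivation_n, case_oversample_factor = 1,
                       seed = 1L) {
  assert_number(derivation_n, "derivation_n", 1)
  assert_number(case_oversample_factor, "case_oversample_factor", 1)
  structure(list(derivation_n = as.integer(derivation_n),
                 case_oversample_factor = case_oversample_factor,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into an event-oversampled derivation set and a weighted
#' validation set
#'
#' Cases (records with `event == 1`, or a caller-supplied indicator) are
#' selected into the derivation set with `case_oversample_factor` times
#' the control selection probability, normalised so the expected
#' derivation size equals `derivation_n`. The validation set is the
#' complement; its `weight` column holds the inverse probability of
#' remaining in the validation set, `1 / (1 - p_select)`.
#'
#' @param records A [survival_records()] data frame.
#' @param spec A [split_spec()].
#' @param case Optional logical/0-1 case indicator (default
#'   `records$event == 1`).
#' @return List with `derivation`, `validation` (weights replaced by the
#'   selection weights) and `selection_prob` (per-record).
#' @export
split_oversampled <- function(records, spec, case = NULL) {
  if (is.null(case)) case <- records$event == 1
  case <- as.logical(case)
  n1 <- sum(case)
  n0 <- sum(!case)
  if (spec$derivation_n >= nrow(records)) {
    stop_validation("derivation_n must be smaller than the cohort")
  }
  p_control <- spec$derivation_n / (n0 + spec$case_oversample_factor * n1)
  p_case <- spec$case_oversample_factor * p_control
  if (p_case > 1) {
    stop_validation("oversample factor implies case selection probability %.3f > 1",
                    p_case)
  }
  p <- ifelse(case, p_case, p_control)
  sel <- with_seed(spec$seed, runif(nrow(records)) < p)
  derivation <- records[sel, , drop = FALSE]
  validation <- records[!sel, , drop = FALSE]
  validation$weight <- 1 / (1 - p[!sel])
  cap <- attr(records, "admin_cap")
  if (is.null(cap)) cap <- 75
  list(derivation = survival_records(derivation, admin_cap = cap),
       validation = survival_records(validation, admin_cap = cap),
       selection_prob = p)
}

#' Simulate a full cohort: genotypes, liabilities, risk factors and
#' survival
#'
#' Convenience wrapper tying the generators together. The first trait in
#' the architecture is the outcome: its liability (genetic value plus
#' `N(0, 1 - h2)` noise) drives the hazard with per-SD log hazard ratio
#' `loghr_liability`, alongside vascular risk factors (SBP, BMI, smoking,
#' diabetes) whose distributions emulate a middle-aged population cohort.
#' Measured SBP is lowered by 15 mm Hg in treated individuals so that the
#' `+15` adjustment of [derive_risk_factors()] reconstructs the
#' underlying value. Sex strata have distinct baseline hazards.
#'
#' @param spec An [architecture_spec()].
#' @param n_samples Cohort size.
#' @param gwas_n External-GWAS sample sizes passed to
#'   [simulate_sumstats()].
#' @param loghr_liability Per-SD log hazard ratio of the outcome-trait
#'   liability (default `log(1.26)`).
#' @param loghr_factors Named per-SD log hazard ratios for risk-factor
#'   columns (default SBP 1.28, BMI 1.10, smoking 1.25, diabetes 1.15 on
#'   the HR scale).
#' @param baseline_shape,baseline_rate,followup_years,admin_cap Passed to
#'   [simulate_survival()]; the female stratum is the reference rate and
#'   males have a 2.2-fold baseline rate.
#' @param seed Master seed (default the spec seed).
#' @return A `sim_cohort` list: `genotypes`, `liability` (samples x
#'   traits), `sumstats`, `factors`, `records`, `prevalent`, `truth`.
#' @export
simulate_cohort <- function(spec, n_samples, gwas_n = 100000,
                            loghr_liability = log(1.26),
                            loghr_factors = c(sbp = log(1.28),
                                              bmi = log(1.10),
                                              smoker = log(1.25),
                                              diabetes = log(1.15)),
                            baseline_shape = 0.09, baseline_rate = 2e-6,
                            followup_years = 7, admin_cap = 75,
                            seed = spec$seed) {
  geno <- simulate_genotypes(spec, n_samples,
                             seed = derive_seed(seed, "cohort-genotypes"))
  arch <- simulate_architecture(spec)
  sumstats <- simulate_sumstats(arch, spec, gwas_n)
  K <- nrow(spec$traits)
  G <- geno$dosages %*% arch$effects

  sim <- with_seed(derive_seed(seed, "cohort-phenotypes"), {
    liab <- G + matrix(rnorm(n_samples * K), n_samples, K) %*%
      diag(sqrt(pmax(1 - spec$traits$h2, 0)), K)
    colnames(liab) <- spec$traits$label
    outcome_liab <- liab[, 1L]

    sex <- ifelse(runif(n_samples) < 0.457, "male", "female")
    z_help <- 0.25 * scale(outcome_liab)[, 1L] +
      sqrt(1 - 0.25^2) * rnorm(n_samples)
    sbp_true <- 138 + 20 * z_help
    dbp <- 82 + 10 * (0.7 * z_help + sqrt(1 - 0.49) * rnorm(n_samples))
    bmi <- 27.4 + 4.8 * rnorm(n_samples)
    ldl <- 3.6 + 0.87 * rnorm(n_samples)
    smoker <- as.integer(runif(n_samples) < 0.10)
    diabetes <- as.integer(runif(n_samples) < 0.047)
    bp_med <- as.integer(runif(n_samples) <
                           plogis(qlogis(0.205) + 0.8 * scale(sbp_true)[, 1L]))
    lipid_med <- as.integer(runif(n_samples) <
                              plogis(qlogis(0.169) + 0.5 * scale(ldl)[, 1L]))
    hyp_rec <- as.integer(runif(n_samples) < 0.02)
    factors <- data.frame(
      sample_id = geno$sample_ids, stratum = sex,
      sbp = sbp_true - 15 * bp_med,  # measured under treatment
      dbp = dbp, bmi = bmi, ldl = ldl, smoker = smoker,
      diabetes = diabetes, bp_med = bp_med, lipid_med = lipid_med,
      hypertension_record = hyp_rec, stringsAsFactors = FALSE)
    factors <- derive_risk_factors(factors)
    factors$liability <- outcome_liab
    list(liab = liab, factors = factors)
  })

  loghr <- c(liability = unname(loghr_liability))
  fac_map <- c(sbp = "sbp_adjusted", bmi = "bmi", smoker = "smoker",
               diabetes = "diabetes")
  for (f in names(loghr_factors)) {
    col <- if (f %in% names(fac_map)) fac_map[[f]] else f
    loghr[[col]] <- unname(loghr_factors[[f]])
  }
  surv <- simulate_survival(
    sim$factors, loghr = loghr, baseline_shape = baseline_shape,
    baseline_rate = baseline_rate,
    stratum_rate_ratio = c(female = 1, male = 2.2),
    followup_years = followup_years, admin_cap = admin_cap,
    seed = derive_seed(seed, "cohort-survival"))

  structure(list(genotypes = geno, liability = sim$liab,
                 sumstats = sumstats, factors = sim$factors,
                 records = surv$records, prevalent = surv$prevalent,
                 truth = list(effects = arch$effects, causal = arch$causal,
                              loghr = loghr, survival = surv$truth)),
            class = "sim_cohort")
}
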