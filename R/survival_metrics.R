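#' Construct validated survival records
#'
#' Container for left-truncated, administratively censored time-to-event
#' records with age as the time scale: entry at assessment age, exit at
#' event/censoring age, an optional sex stratum and inverse-probability
#' selection weights.
#'
#' @param df Data frame with `sample_id`, `entry_age`, `exit_age`, `event`
#'   (0/1) and optionally `stratum` (default `"all"`), `weight`
#'   (default 1) plus covariate columns.
#' @param admin_cap Administrative censoring age; `exit_age` may not
#'   exceed it (default 75).
#' @return A `survival_records` data frame.
#' @export
survival_records <- function(df, admin_cap = 75) {
  assert_columns(df, c("sample_id", "entry_age", "exit_age", "event"),
                 "survival records")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"stratum" %in% names(df)) df$stratum <- "all"
  if (!"weight" %in% names(df)) df$weight <- 1
  if (any(df$exit_age <= df$entry_age)) {
    stop_validation("exit_age must exceed entry_age for every record")
  }
  if (any(df$exit_age > admin_cap + 1e-9)) {
    stop_validation("exit_age exceeds the administrative cap (%g)", admin_cap)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop_validation("event must be 0/1")
  }
  if (any(df$weight <= 0)) stop_validation("weights must be positive")
  rownames(df) <- NULL
  structure(df, admin_cap = admin_cap,
            class = c("survival_records", "data.frame"))
}

#' Fit a left-truncated, stratified, weighted Cox model
#'
#' Age is the time scale: the risk set at age t contains records with
#' `entry_age < t <= exit_age`. The model is stratified by the `stratum`
#' column, weighted by the `weight` column, uses the Efron tie
#' approximation, and reports sandwich (robust) standard errors. The
#' baseline cumulative hazard is the Breslow estimator per stratum, and
#' the global scaled-Schoenfeld-residual test (identity time transform) is
#' attached.
#'
#' @param records A [survival_records()] data frame whose columns include
#'   every predictor.
#' @param predictor_names Character vector of predictor column names (may
#'   include factors).
#' @return A `cox_result`: list with `beta`, `robust_se`,
#'   `baseline_cumhaz` (data frame `stratum`, `time`, `cumhaz` at the zero
#'   covariate vector), `schoenfeld_p`, `loglik`, `n`, `n_event`, and the
#'   underlying `fit`.
#' @export
fit_cox <- function(records, predictor_names) {
  assert_columns(records, predictor_names, "records")
  if (sum(records$event) == 0) {
    stop_classed("metagrs_degenerate_fit_error", "no events in records")
  }
  ev_by_stratum <- tapply(records$event, records$stratum, sum)
  if (any(ev_by_stratum == 0)) {
    stop_classed("metagrs_degenerate_fit_error",
                 "stratum without events: %s",
                 paste(names(ev_by_stratum)[ev_by_stratum == 0],
                       collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(entry_age, exit_age, event) ~",
    paste(predictor_names, collapse = " + "),
    "+ survival::strata(stratum)"))
  fit <- survival::coxph(fml, data = records, weights = records$weight,
                         cluster = records$sample_id, robust = TRUE,
                         ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  if (anyNA(coef(fit))) {
    stop_classed("metagrs_iteration_limit_error",
                 "Cox fit failed: NA coefficients for %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  beta <- coef(fit)
  robust_se <- sqrt(diag(fit$var))
  names(robust_se) <- names(beta)
  bh <- survival::basehaz(fit, centered = FALSE)
  if (!"strata" %in% names(bh)) bh$strata <- records$stratum[1L]
  baseline <- data.frame(stratum = sub("^.*=", "", as.character(bh$strata)),
                         time = bh$time, cumhaz = bh$hazard,
                         stringsAsFactors = FALSE)
  schoenfeld_p <- tryCatch(
    survival::cox.zph(fit, transform = "identity",
                      global = TRUE)$table["GLOBAL", "p"],
    error = function(e) NA_real_)
  structure(list(beta = beta, robust_se = robust_se,
                 baseline_cumhaz = baseline, schoenfeld_p = schoenfeld_p,
                 loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_event = fit$nevent, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, Schoenfeld global p = %.3g\n",
              x$n, x$n_event, x$schoenfeld_p))
  print(data.frame(loghr = x$beta, robust_se = x$robust_se,
                   hr = exp(x$beta)))
  invisible(x)
}

#' Hazard ratio per standard deviation of a predictor
#'
#' For a predictor entered in SD units, returns `exp(beta)` with the
#' robust-SE Wald 95% confidence interval.
#'
#' @param result A `cox_result`.
#' @param predictor Coefficient name.
#' @return Named numeric vector `(hr, lower, upper)`.
#' @export
hr_per_sd <- function(result, predictor) {
  if (!predictor %in% names(result$beta)) {
    stop_validation("predictor `%s` not in model", predictor)
  }
  b <- result$beta[[predictor]]
  se <- result$robust_se[[predictor]]
  c(hr = exp(b), lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se))
}

#' Percentile-bin specification
#'
#' @param edges Strictly increasing cumulative-percentile cut points
#'   starting at 0 and ending at 1.
#' @param reference Two-element vector giving the reference bin as an
#'   `(low, high)` percentile pair; must equal one of the bins (default
#'   the middle 45--55% bin).
#' @return A `percentile_bins` list.
#' @export
percentile_bins <- function(edges, reference = c(0.45, 0.55)) {
  if (is.unsorted(edges, strictly = TRUE) || edges[1L] != 0 ||
      edges[length(edges)] != 1) {
    stop_validation("edges must strictly increase from 0 to 1")
  }
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  ref_idx <- which(abs(lo - reference[1L]) < 1e-12 &
                     abs(hi - reference[2L]) < 1e-12)
  if (length(ref_idx) != 1L) {
    stop_validation("reference bin (%g, %g) is not one of the bins",
                    reference[1L], reference[2L])
  }
  structure(list(edges = edges, reference = reference, ref_idx = ref_idx),
            class = "percentile_bins")
}

#' Hazard ratios for score percentile bins versus a reference bin
#'
#' Cuts the score into the specified percentile bins, fits one Cox model
#' with bin membership as a categorical predictor (same stratification and
#' weighting as [fit_cox()]) with the reference bin as baseline, and
#' returns per-bin hazard ratios.
#'
#' @param scores A [score_vector()] covering the record sample ids.
#' @param records A [survival_records()] data frame.
#' @param spec A [percentile_bins()].
#' @return Data frame with `bin`, `lo_pct`, `hi_pct`, `n`, `n_event`,
#'   `hr`, `lower`, `upper` and a `reference` flag.
#' @export
percentile_bin_hr <- function(scores, records, spec) {
  x <- scores$raw[match(records$sample_id, scores$sample_ids)]
  if (anyNA(x)) stop_validation("records contain samples without scores")
  breaks <- quantile(x, probs = spec$edges, type = 7)
  breaks[1L] <- -Inf
  breaks[length(breaks)] <- Inf
  lo <- spec$edges[-length(spec$edges)]
  hi <- spec$edges[-1L]
  lab <- sprintf("%g-%g%%", 100 * lo, 100 * hi)
  bin <- cut(x, breaks = breaks, labels = lab, include.lowest = TRUE)
  if (any(table(bin) == 0)) {
    stop_validation("empty percentile bin; widen the bins or the sample")
  }
  df <- records
  df$score_bin <- stats::relevel(bin, ref = lab[spec$ref_idx])
  res <- fit_cox(df, "score_bin")
  out <- data.frame(bin = lab, lo_pct = 100 * lo, hi_pct = 100 * hi,
                    n = as.integer(table(bin)[lab]),
                    n_event = as.integer(tapply(df$event, bin, sum)[lab]),
                    hr = 1, lower = NA_real_, upper = NA_real_,
                    reference = seq_along(lab) == spec$ref_idx,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lab)) {
    if (i == spec$ref_idx) next
    cf <- paste0("score_bin", lab[i])
    ci <- hr_per_sd(res, cf)
    out$hr[i] <- ci[["hr"]]
    out$lower[i] <- ci[["lower"]]
    out$upper[i] <- ci[["upper"]]
  }
  attr(out, "cox_result") <- res
  out
}

#' Harrell's concordance index under left truncation
#'
#' Concordance over usable pairs: a pair is comparable when one member's
#' event age falls strictly inside the other's at-risk window
#' `(entry_age, exit_age]`; score ties count 0.5 and pairs of tied event
#' ages are not compared. The confidence interval uses the
#' infinitesimal-jackknife variance of the concordance estimator.
#'
#' @param records A [survival_records()] data frame.
#' @param risk_score Numeric vector (higher = higher predicted risk)
#'   aligned with the record rows.
#' @return Named numeric vector `(c, lower, upper, se)`.
#' @export
harrell_c <- function(records, risk_score) {
  if (length(risk_score) != nrow(records)) {
    stop_validation("risk_score length must match records")
  }
  df <- data.frame(entry_age = records$entry_age,
                   exit_age = records$exit_age, event = records$event,
                   score = risk_score, w = records$weight)
  cc <- survival::concordance(
    survival::Surv(entry_age, exit_age, event) ~ score,
    data = df, weights = df$w, reverse = TRUE)
  cnt <- cc$count
  if (sum(cnt[c("concordant", "discordant", "tied.x")]) == 0) {
    stop_validation("no comparable pairs")
  }
  se <- sqrt(cc$var)
  c(c = cc$concordance, lower = cc$concordance - 1.96 * se,
    upper = cc$concordance + 1.96 * se, se = se)
}

# log-rank statistic with delayed entry: risk set at event age t is
# {entry < t <= exit}; covariance of (O - E) accumulated per event time
logrank_delayed <- function(entry, exit, event, group) {
  group <- factor(group)
  G <- nlevels(group)
  times <- sort(unique(exit[event == 1]))
  OmE <- numeric(G - 1L)
  V <- matrix(0, G - 1L, G - 1L)
  for (t in times) {
    at_risk <- entry < t & exit >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & exit == t)
    if (n_t < 2L || d_t == 0L) next
    n_g <- tabulate(group[at_risk], nbins = G)
    d_g <- tabulate(group[event == 1 & exit == t], nbins = G)
    e_g <- d_t * n_g / n_t
    OmE <- OmE + (d_g - e_g)[seq_len(G - 1L)]
    frac <- d_t * (n_t - d_t) / (n_t - 1)
    for (a in seq_len(G - 1L)) {
      for (b in seq_len(G - 1L)) {
        V[a, b] <- V[a, b] + frac *
          ((a == b) * n_g[a] * n_t - n_g[a] * n_g[b]) / n_t^2
      }
    }
  }
  qr_V <- qr(V)
  if (qr_V$rank < G - 1L) {
    chisq <- NA_real_
    p <- NA_real_
  } else {
    chisq <- drop(t(OmE) %*% solve(qr_V, OmE))
    p <- stats::pchisq(chisq, df = G - 1L, lower.tail = FALSE)
  }
  list(chisq = chisq, df = G - 1L, p = p)
}

#' Kaplan-Meier curves with delayed entry and a log-rank test
#'
#' Product-limit estimator per group with left truncation at `entry_age`,
#' plus the standard log-rank statistic across groups (risk sets honour
#' delayed entry).
#'
#' @param records A [survival_records()] data frame.
#' @param groups Factor (or coercible) aligned with the record rows.
#' @return List with `curves` (data frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `logrank_chisq`, `logrank_df`, `logrank_p`, and
#'   the underlying `fit`.
#' @export
kaplan_meier <- function(records, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(records)) {
    stop_validation("groups length must match records")
  }
  if (any(table(groups) == 0)) stop_validation("empty group")
  df <- data.frame(entry_age = records$entry_age,
                   exit_age = records$exit_age,
                   event = records$event, group = groups)
  fit <- survival::survfit(
    survival::Surv(entry_age, exit_age, event) ~ group, data = df)
  strata_names <- if (is.null(fit$strata)) levels(groups) else
    sub("^group=", "", names(fit$strata))
  reps <- if (is.null(fit$strata)) length(fit$time) else fit$strata
  curves <- data.frame(group = rep(strata_names, reps), time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  lr <- if (nlevels(groups) >= 2L) {
    logrank_delayed(df$entry_age, df$exit_age, df$event, df$group)
  } else {
    list(chisq = NA_real_, df = 0L, p = NA_real_)
  }
  list(curves = curves, logrank_chisq = lr$chisq, logrank_df = lr$df,
       logrank_p = lr$p, fit = fit)
}

#' Predicted cumulative incidence for a covariate profile
#'
#' Evaluates `1 - exp(-H0(t) * exp(x' beta))` per stratum from the fitted
#' Cox model, using the Breslow baseline cumulative hazard, at the ages in
#' `t_grid`. Confidence intervals are propagated on the log cumulative
#' hazard scale. Ages beyond the last observed event time draw a warning
#' and the curve is flat thereafter.
#'
#' @param result A `cox_result` from [fit_cox()].
#' @param profile One-row data frame covering every model predictor.
#' @param t_grid Ages at which to evaluate the curve.
#' @return Data frame with `stratum`, `t`, `risk`, `lower`, `upper`.
#' @export
cumulative_incidence <- function(result, profile, t_grid) {
  if (nrow(profile) != 1L) stop_validation("profile must be a single row")
  sf <- survival::survfit(result$fit, newdata = profile, ctype = 1)
  strata_names <- if (is.null(sf$strata)) "all" else
    sub("^.*=", "", names(sf$strata))
  reps <- if (is.null(sf$strata)) length(sf$time) else sf$strata
  stratum <- rep(strata_names, reps)
  cumhaz <- as.vector(sf$cumhaz)
  se_ch <- as.vector(sf$std.err)
  out <- list()
  for (s in unique(stratum)) {
    sel <- stratum == s
    tt <- sf$time[sel]
    H <- cumhaz[sel]
    SE <- se_ch[sel]
    ev_max <- if (any(sf$n.event[sel] > 0)) max(tt[sf$n.event[sel] > 0]) else max(tt)
    if (any(t_grid > ev_max)) {
      warning(sprintf(
        "t beyond last event age (%.1f) in stratum %s: curve held flat",
        ev_max, s))
    }
    idx <- findInterval(t_grid, tt)
    H_t <- ifelse(idx == 0, 0, H[pmax(idx, 1L)])
    SE_t <- ifelse(idx == 0, 0, SE[pmax(idx, 1L)])
    lo <- hi <- numeric(length(t_grid))
    pos <- H_t > 0
    lo[pos] <- H_t[pos] * exp(-1.96 * SE_t[pos] / H_t[pos])
    hi[pos] <- H_t[pos] * exp(1.96 * SE_t[pos] / H_t[pos])
    out[[s]] <- data.frame(stratum = s, t = t_grid,
                           risk = 1 - exp(-H_t),
                           lower = 1 - exp(-lo), upper = 1 - exp(-hi),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decile calibration with baseline-rate rescaling
#'
#' Rescales predicted probabilities on the odds scale by `1 / rate_ratio`
#' (a logistic intercept shift of `-log(rate_ratio)`, transporting a model
#' fitted in an event-enriched derivation set to a cohort whose baseline
#' event rate is `rate_ratio`-fold lower), cuts samples into deciles of
#' the rescaled prediction, and compares mean predicted risk with the
#' observed event proportion per decile, with exact binomial confidence
#' intervals.
#'
#' @param predicted_risk Per-sample predicted probabilities in (0, 1).
#' @param observed Binary outcomes.
#' @param rate_ratio Fold difference between the derivation-set and
#'   target-cohort baseline event rates (> 0; 1 = no rescaling).
#' @return Data frame with `decile`, `n`, `n_event`, `mean_predicted`,
#'   `observed`, `lower`, `upper`.
#' @export
calibration_by_decile <- function(predicted_risk, observed,
                                  rate_ratio = 1) {
  assert_number(rate_ratio, "rate_ratio", 0, Inf, open_lower = TRUE)
  if (any(predicted_risk <= 0 | predicted_risk >= 1)) {
    stop_validation("predicted_risk must lie strictly in (0, 1)")
  }
  odds <- predicted_risk / (1 - predicted_risk) / rate_ratio
  p <- odds / (1 + odds)
  breaks <- unique(quantile(p, probs = seq(0, 1, by = 0.1), type = 7))
  if (length(breaks) < 2L) {
    bin <- factor(rep(1L, length(p)))
  } else {
    bin <- cut(p, breaks = breaks, include.lowest = TRUE,
               labels = FALSE)
    bin <- factor(bin)
  }
  rows <- lapply(levels(bin), function(b) {
    sel <- bin == b
    n <- sum(sel)
    ev <- sum(observed[sel])
    bt <- binom.test(ev, n)
    data.frame(decile = as.integer(b), n = n, n_event = ev,
               mean_predicted = mean(p[sel]), observed = ev / n,
               lower = bt$conf.int[1L], upper = bt$conf.int[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wald test for a predictor-by-predictor interaction
#'
#' Adds the product term `a:b` to a Cox model (stratified and weighted as
#' in [fit_cox()]) or a logistic model of the event indicator, and returns
#' the Wald p-value for the interaction coefficient (robust SE for the
#' Cox model).
#'
#' @param records A [survival_records()] data frame containing both
#'   predictors.
#' @param predictor_a,predictor_b Column names.
#' @param model `"cox"` or `"logistic"`.
#' @return List with `p`, `coef`, `se`, `model`.
#' @export
test_interaction <- function(records, predictor_a, predictor_b,
                             model = c("cox", "logistic")) {
  model <- match.arg(model)
  assert_columns(records, c(predictor_a, predictor_b), "records")
  a <- records[[predictor_a]]
  b <- records[[predictor_b]]
  if (sd(as.numeric(b)) == 0 || sd(as.numeric(a)) == 0) {
    stop_validation("interaction predictors must be non-constant")
  }
  prod_resid <- stats::residuals(lm(I(as.numeric(a) * as.numeric(b)) ~
                                      as.numeric(a) + as.numeric(b)))
  if (sd(prod_resid) < 1e-12) {
    stop_validation("product term is collinear with its main effects")
  }
  if (model == "cox") {
    df <- records
    df$interaction_ab <- as.numeric(a) * as.numeric(b)
    res <- fit_cox(df, c(predictor_a, predictor_b, "interaction_ab"))
    z <- res$beta[["interaction_ab"]] / res$robust_se[["interaction_ab"]]
    list(p = 2 * pnorm(-abs(z)), coef = res$beta[["interaction_ab"]],
         se = res$robust_se[["interaction_ab"]], model = "cox")
  } else {
    fml <- stats::as.formula(paste("event ~", predictor_a, "*", predictor_b))
    fit <- glm(fml, family = stats::binomial(), data = records)
    sm <- summary(fit)$coefficients
    cname <- grep(":", rownames(sm), value = TRUE)[1L]
    list(p = sm[cname, "Pr(>|z|)"], coef = sm[cname, "Estimate"],
         se = sm[cname, "Std. Error"], model = "logistic")
  }
}
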