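#' Configuration for cross-validated elastic-net stacking
#'
#' @param n_folds Number of cross-validation folds (>= 2; default 10).
#' @param alpha_grid Elastic-net mixing parameters to evaluate.
#' @param n_lambda Number of penalty strengths per mixing value, auto-scaled
#'   from the data by glmnet.
#' @param seed Integer seed controlling fold assignment.
#' @param cv_metric `"pooled"` computes one AUC per penalty from held-out
#'   predictions pooled across folds; `"fold_mean"` averages per-fold AUCs.
#' @param stratified Stratify fold assignment by case status (default TRUE).
#' @return A `stack_config` list.
#' @export
stack_config <- function(n_folds = 10L, alpha_grid = c(0.1, 0.5, 0.9),
                         n_lambda = 20L, seed = 1L,
                         cv_metric = c("pooled", "fold_mean"),
                         stratified = TRUE) {
  assert_number(n_folds, "n_folds", 2)
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop_validation("alpha_grid values must lie in [0, 1]")
  }
  assert_number(n_lambda, "n_lambda", 2)
  assert_flag(stratified, "stratified")
  structure(list(n_folds = as.integer(n_folds), alpha_grid = alpha_grid,
                 n_lambda = as.integer(n_lambda), seed = as.integer(seed),
                 cv_metric = match.arg(cv_metric), stratified = stratified),
            class = "stack_config")
}

# Wilcoxon (rank) formulation of the area under the ROC curve
auc_stat <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stack standardised component scores by cross-validated elastic-net
#' logistic regression
#'
#' Fits penalised logistic regressions of a binary outcome on K
#' standardised component scores (penalised) plus optional covariates
#' (unpenalised) over a grid of elastic-net mixing/strength values,
#' evaluates each grid point by held-out AUC over seeded
#' case-status-stratified folds, and refits the AUC-maximising penalty on
#' the full data. Samples are canonicalised by sample id before fold
#' assignment and fitting, so results are invariant to input row order.
#'
#' @param components Named list of K standardised [score_vector()]s over
#'   the same samples (their `scale` fields supply the sigma_k used by
#'   [collapse_weights()]).
#' @param outcome Binary 0/1 vector aligned with the component sample
#'   order.
#' @param covariates Optional data frame/matrix of unpenalised adjustment
#'   covariates, same row order.
#' @param config A [stack_config()].
#' @return A `meta_model`: list with `gamma` (per-component log-odds),
#'   `sigma`, `covariate_coefs`, `intercept`, `chosen_penalty`
#'   (`alpha`, `lambda`), `cv_auc_trace` (data frame `alpha`, `lambda`,
#'   `auc`), `foldid` (named by sample id), `cv_links` (held-out linear
#'   predictors per grid point) and `component_labels`.
#' @export
fit_stack_cv <- function(components, outcome, covariates = NULL,
                         config = stack_config()) {
  K <- length(components)
  if (K < 1L) stop_validation("need at least one component score")
  labels <- names(components)
  if (is.null(labels)) labels <- paste0("GRS", seq_len(K))
  ids <- components[[1L]]$sample_ids
  for (s in components) {
    if (!identical(s$sample_ids, ids)) {
      stop_validation("components must cover the same samples in the same order")
    }
    if (is.null(s$std)) stop_validation("components must be standardised")
  }
  n <- length(ids)
  if (length(outcome) != n) stop_validation("outcome length mismatch")
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop_validation("outcome must contain both classes")
  }
  if (n < config$n_folds) stop_validation("fewer samples than folds")

  # canonical sample order: invariant to how the caller permuted rows
  ord <- order(ids)
  ids_c <- ids[ord]
  y <- as.numeric(outcome)[ord]
  S <- vapply(components, function(s) s$std, numeric(n))[ord, , drop = FALSE]
  colnames(S) <- labels
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)[ord, , drop = FALSE]
    if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
  }
  X <- cbind(S, Z)
  pf <- c(rep(1, K), rep(0, if (is.null(Z)) 0L else ncol(Z)))
  if (ncol(X) < 2L) {
    # glmnet requires >= 2 columns; pad with an inert zero column
    X <- cbind(X, `.dummy` = 0)
    pf <- c(pf, 0)
  }

  foldid <- integer(n)
  with_seed(config$seed, {
    if (config$stratified) {
      for (cls in unique(y)) {
        sel <- which(y == cls)
        foldid[sel] <- sample(rep_len(seq_len(config$n_folds), length(sel)))
      }
    } else {
      foldid <- sample(rep_len(seq_len(config$n_folds), n))
    }
  })

  trace <- list()
  links <- list()
  for (alpha in config$alpha_grid) {
    full <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                           nlambda = config$n_lambda, penalty.factor = pf,
                           standardize = FALSE)
    lambdas <- full$lambda
    held <- matrix(NA_real_, n, length(lambdas))
    for (f in seq_len(config$n_folds)) {
      test <- foldid == f
      fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            family = "binomial", alpha = alpha,
                            lambda = lambdas, penalty.factor = pf,
                            standardize = FALSE)
      held[test, ] <- predict(fit, X[test, , drop = FALSE], type = "link")
    }
    auc <- if (config$cv_metric == "pooled") {
      apply(held, 2L, auc_stat, y = y)
    } else {
      sapply(seq_along(lambdas), function(l) {
        mean(vapply(seq_len(config$n_folds), function(f) {
          auc_stat(held[foldid == f, l], y[foldid == f])
        }, numeric(1)), na.rm = TRUE)
      })
    }
    key <- sprintf("alpha=%g", alpha)
    links[[key]] <- held
    trace[[key]] <- data.frame(alpha = alpha, lambda = lambdas, auc = auc)
  }
  trace <- do.call(rbind, c(trace, make.row.names = FALSE))
  best <- which.max(trace$auc)
  chosen <- list(alpha = trace$alpha[best], lambda = trace$lambda[best])

  refit <- glmnet::glmnet(X, y, family = "binomial", alpha = chosen$alpha,
                          lambda = chosen$lambda, penalty.factor = pf,
                          standardize = FALSE)
  beta <- drop(as.matrix(coef(refit)))
  gamma <- beta[labels]
  sigma <- vapply(components, function(s) s$scale, numeric(1))
  names(sigma) <- labels
  cov_coefs <- if (is.null(Z)) numeric(0) else beta[colnames(Z)]

  structure(list(gamma = gamma, sigma = sigma,
                 covariate_coefs = cov_coefs,
                 intercept = unname(beta["(Intercept)"]),
                 chosen_penalty = chosen, cv_auc_trace = trace,
                 foldid = setNames(foldid, ids_c), cv_links = links,
                 component_labels = labels, config = config),
            class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("<meta_model> %d components; alpha = %g, lambda = %.4g, CV AUC = %.4f\n",
              length(x$gamma), x$chosen_penalty$alpha, x$chosen_penalty$lambda,
              max(x$cv_auc_trace$auc, na.rm = TRUE)))
  print(round(data.frame(gamma = x$gamma, sigma = x$sigma), 4))
  invisible(x)
}

#' Collapse a fitted stack to a single per-SNP weight table
#'
#' Computes `weight_j = sum_k (gamma_k / sigma_k) * alpha_jk` over the
#' union of all component variants, where `alpha_jk` is the per-allele
#' effect of SNP j in component k and is zero when the SNP is absent from
#' that component. Scoring a cohort with the collapsed table reproduces
#' the gamma-weighted sum of standardised component scores up to one
#' additive constant (the dropped standardisation means).
#'
#' @param model A `meta_model` from [fit_stack_cv()].
#' @param components Named list of component weight tables (the retained
#'   `sumstats` subsets, one per component, mutually harmonized to one
#'   allele frame), in the order of `model$component_labels`.
#' @return A `snp_weights` data frame (`chrom`, `pos`, `id`,
#'   `effect_allele`, `other_allele`, `weight`) with all nonzero collapsed
#'   weights.
#' @export
collapse_weights <- function(model, components) {
  K <- length(model$gamma)
  if (length(components) != K) {
    stop_validation("model has %d components but %d weight tables supplied",
                    K, length(components))
  }
  if (!is.null(names(components)) &&
      !identical(names(components), model$component_labels)) {
    components <- components[model$component_labels]
  }
  frames <- lapply(components, function(w) {
    wcol <- if ("beta" %in% names(w)) "beta" else "weight"
    assert_columns(w, c("chrom", "pos", "id", "effect_allele",
                        "other_allele", wcol), "component weights")
    data.frame(chrom = w$chrom, pos = w$pos, id = w$id,
               effect_allele = w$effect_allele,
               other_allele = w$other_allele, alpha = w[[wcol]],
               stringsAsFactors = FALSE)
  })
  all_v <- do.call(rbind, frames)
  key <- paste(all_v$chrom, all_v$pos)
  uni <- !duplicated(key)
  frame_alleles <- paste(all_v$effect_allele, all_v$other_allele)
  ref_alleles <- frame_alleles[match(key, key)]  # first occurrence per key
  if (any(frame_alleles != ref_alleles)) {
    bad <- key[frame_alleles != ref_alleles][1L]
    stop_classed("metagrs_harmonization_error",
                 "components disagree on the allele frame at %s", bad)
  }
  union_v <- all_v[uni, c("chrom", "pos", "id", "effect_allele",
                          "other_allele")]
  ukey <- key[uni]
  weight <- numeric(nrow(union_v))
  for (k in seq_len(K)) {
    fk <- frames[[k]]
    idx <- match(paste(fk$chrom, fk$pos), ukey)
    weight[idx] <- weight[idx] +
      (model$gamma[k] / model$sigma[k]) * fk$alpha
  }
  out <- union_v
  out$weight <- weight
  out <- out[out$weight != 0, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("snp_weights", "data.frame"))
}

#' QC-sensitivity refit of the collapsed score
#'
#' Applies a variant QC filter to every component, re-collapses the
#' per-SNP weights, and reports the hazard ratio per standard deviation of
#' the collapsed score on a supplied cohort before and after filtering.
#'
#' @param model A `meta_model`.
#' @param components Component weight tables carrying `eaf` (and `info`
#'   when `spec$info_min > 0`) annotations.
#' @param spec A [qc_filter()].
#' @param genotypes Cohort [genotype_matrix()] used for scoring.
#' @param records Cohort [survival_records()] used for the Cox fits.
#' @return List with `weights_before`, `weights_after`, `hr_before`,
#'   `hr_after` (each `(hr, lower, upper)`), and `delta_log_hr`.
#' @export
sensitivity_qc_refit <- function(model, components, spec, genotypes,
                                 records) {
  filtered <- lapply(components, apply_variant_qc, spec = spec)
  before <- collapse_weights(model, components)
  after <- collapse_weights(model, filtered)
  hr_of <- function(wtab) {
    sv <- standardize(score_samples(genotypes, wtab))
    df <- records
    df$metagrs <- sv$std[match(df$sample_id, sv$sample_ids)]
    hr_per_sd(fit_cox(df, "metagrs"), "metagrs")
  }
  hr_before <- hr_of(before)
  hr_after <- hr_of(after)
  list(weights_before = before, weights_after = after,
       hr_before = hr_before, hr_after = hr_after,
       delta_log_hr = log(hr_after[["hr"]]) - log(hr_before[["hr"]]))
}
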