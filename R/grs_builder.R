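#' LD-pruning parameters
#'
#' @param window_kb Window width in kilobases over which pairwise LD is
#'   examined (>= 1).
#' @param step Window-advance granularity in variants; retained for
#'   interface compatibility with `--indep-pairwise`-style tools. With the
#'   keep-earlier tie-break used here the kept set is identical for any
#'   positive `step`, so it does not alter results.
#' @param r2_max Maximum allowed squared Pearson dosage correlation between
#'   retained variants within a window, in \[0,1\].
#' @return A `prune_params` list.
#' @export
prune_params <- function(window_kb = 250L, step = 5L, r2_max = 0.2) {
  assert_number(window_kb, "window_kb", 1)
  assert_number(step, "step", 1)
  assert_number(r2_max, "r2_max", 0, 1)
  structure(list(window_kb = as.integer(window_kb), step = as.integer(step),
                 r2_max = r2_max), class = "prune_params")
}

#' Greedy LD pruning of a variant panel
#'
#' Left-to-right greedy sweep over variants sorted by (chrom, pos): each
#' variant is dropped if its squared Pearson dosage correlation with any
#' previously retained variant on the same chromosome within `window_kb`
#' exceeds `r2_max`. When a pair violates the threshold the earlier variant
#' by position is kept, making the result deterministic.
#'
#' @param genotypes A [genotype_matrix()] reference panel whose variants
#'   are sorted by (chrom, pos).
#' @param params A [prune_params()].
#' @return Character vector of retained variant ids.
#' @export
greedy_ld_prune <- function(genotypes, params = prune_params()) {
  if (!inherits(params, "prune_params")) {
    params <- do.call(prune_params, as.list(params))
  }
  v <- genotypes$variants
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    stop_validation("variants must be sorted by (chrom, pos) before pruning")
  }
  m <- nrow(v)
  if (m == 0L) return(character(0))
  window_bp <- params$window_kb * 1000
  X <- genotypes$dosages
  kept <- logical(m)
  kept[1L] <- TRUE
  kept_idx <- 1L
  for (j in seq_len(m)[-1L]) {
    near <- kept_idx[v$chrom[kept_idx] == v$chrom[j] &
                       v$pos[j] - v$pos[kept_idx] <= window_bp]
    drop <- FALSE
    for (i in rev(near)) {
      r <- suppressWarnings(cor(X[, i], X[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > params$r2_max) { drop <- TRUE; break }
    }
    if (!drop) {
      kept[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  v$id[kept]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_validation("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(pvalues, method = "BH")
}

#' Threshold a summary-statistic table on p-values or FDR
#'
#' Retains rows with `pvalue <= cutoff` (`p_max` mode) or with
#' Benjamini-Hochberg q-value strictly below `cutoff` (`fdr_max` mode).
#'
#' @param table A `sumstats` table with a `pvalue` column.
#' @param mode `"p_max"` or `"fdr_max"`.
#' @param cutoff Threshold in (0, 1].
#' @return The filtered table.
#' @export
threshold_variants <- function(table, mode = c("p_max", "fdr_max"),
                               cutoff = 0.05) {
  mode <- match.arg(mode)
  assert_number(cutoff, "cutoff", 0, 1, open_lower = TRUE)
  if (!"pvalue" %in% names(table) || anyNA(table$pvalue)) {
    stop_validation("thresholding requires complete p-values")
  }
  keep <- if (mode == "p_max") {
    table$pvalue <= cutoff
  } else {
    bh_fdr(table$pvalue) < cutoff
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_label") <- attr(table, "trait_label")
  if (inherits(table, "sumstats")) class(out) <- class(table)
  out
}

#' Score vector container
#'
#' Holds per-sample raw genomic risk scores and, after [standardize()],
#' the reference-cohort centring constants.
#'
#' @param sample_ids Character vector.
#' @param raw Numeric vector of raw scores, one per sample.
#' @param center,scale Reference-cohort mean and standard deviation
#'   (`NA` until [standardize()] is applied).
#' @return A `score_vector` object; `$std` holds standardised scores once
#'   centring constants are set.
#' @export
score_vector <- function(sample_ids, raw, center = NA_real_,
                         scale = NA_real_) {
  if (length(sample_ids) != length(raw)) {
    stop_validation("sample_ids and raw scores differ in length")
  }
  std <- if (is.na(center) || is.na(scale)) NULL else (raw - center) / scale
  structure(list(sample_ids = as.character(sample_ids),
                 raw = as.numeric(raw), center = center, scale = scale,
                 std = std),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> n = %d, raw mean %.4g, sd %.4g%s\n",
              length(x$raw), mean(x$raw), sd(x$raw),
              if (is.null(x$std)) "" else
                sprintf("; standardised (center %.4g, scale %.4g)",
                        x$center, x$scale)))
  invisible(x)
}

#' Score samples with a per-SNP weight table
#'
#' Computes `raw_i = sum_j dosage_ij * weight_j` over the variants shared
#' between the panel and the weight table (matched on chrom/pos when
#' coordinates are present, otherwise on variant id, requiring the effect
#' allele to agree — harmonize first with [harmonize_alleles()]). Missing
#' dosages are replaced by the variant's panel mean; weight-table variants
#' absent from the panel contribute zero and are counted in the
#' `n_unmatched` attribute.
#'
#' @param genotypes A [genotype_matrix()].
#' @param weights A weight table with `effect_allele`, a `weight` (or
#'   `beta`) column, and `chrom`/`pos` or `id`.
#' @return A [score_vector()] of raw scores.
#' @export
score_samples <- function(genotypes, weights) {
  wcol <- if ("weight" %in% names(weights)) "weight" else "beta"
  assert_columns(weights, c("effect_allele", wcol), "weights")
  v <- genotypes$variants
  if (all(c("chrom", "pos") %in% names(weights))) {
    idx <- match(paste(weights$chrom, weights$pos),
                 paste(v$chrom, v$pos))
  } else {
    idx <- match(weights$id, v$id)
  }
  ok <- !is.na(idx) & weights$effect_allele == v$effect_allele[idx]
  n_unmatched <- sum(!ok)
  if (!any(ok)) {
    stop_classed("metagrs_empty_overlap_error",
                 "no weight-table variants overlap the genotype panel")
  }
  cols <- idx[ok]
  X <- genotypes$dosages[, cols, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  raw <- drop(X %*% weights[[wcol]][ok])
  out <- score_vector(genotypes$sample_ids, raw)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Standardize a score vector against a reference cohort
#'
#' Stores the mean and standard deviation (denominator `n - 1`) of the raw
#' score over the reference samples and applies `(raw - mean) / sd` to the
#' whole vector. Re-applying the stored transform to the reference subset
#' yields mean 0 and sd 1.
#'
#' @param score A [score_vector()].
#' @param reference_ids Samples defining the centring constants (default:
#'   all samples).
#' @return The standardised [score_vector()].
#' @export
standardize <- function(score, reference_ids = score$sample_ids) {
  sel <- score$sample_ids %in% reference_ids
  if (!any(sel)) stop_validation("no reference samples found in score")
  mu <- mean(score$raw[sel])
  sigma <- sd(score$raw[sel])
  if (!is.finite(sigma) || sigma <= 0) {
    stop_classed("metagrs_degenerate_score_error",
                 "reference scores have zero variance")
  }
  score_vector(score$sample_ids, score$raw, center = mu, scale = sigma)
}

#' Build a grid of candidate GRSs over r-squared thresholds
#'
#' For each pruning threshold, prunes the panel, retains summary-statistic
#' rows passing the significance cutoff among pruned-in variants, scores
#' and standardises the tuning cohort, and fits a Cox model of the
#' standardised score on the tuning survival records.
#'
#' @param sumstats A harmonized `sumstats` table.
#' @param genotypes Tuning-cohort [genotype_matrix()] (also the LD
#'   reference).
#' @param records Tuning-cohort [survival_records()].
#' @param r2_grid Pruning thresholds to evaluate (default
#'   `c(0.1, 0.2, 0.5, 0.8)`).
#' @param window_kb,step Passed to [prune_params()].
#' @param mode,cutoff Passed to [threshold_variants()].
#' @return A `candidate_grid`: list of entries with `r2_max`, `weights`
#'   (the retained `sumstats` subset), `loghr`, `se`, `n_variants`.
#' @export
build_candidate_grid <- function(sumstats, genotypes, records,
                                 r2_grid = c(0.1, 0.2, 0.5, 0.8),
                                 window_kb = 250L, step = 5L,
                                 mode = "p_max", cutoff = 0.05) {
  entries <- lapply(sort(r2_grid), function(r2) {
    kept <- greedy_ld_prune(genotypes,
                            prune_params(window_kb, step, r2_max = r2))
    cand <- threshold_variants(sumstats, mode = mode, cutoff = cutoff)
    cand <- cand[cand$id %in% kept, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    sv <- standardize(score_samples(genotypes, cand))
    df <- records
    df$grs <- sv$std[match(df$sample_id, sv$sample_ids)]
    fit <- fit_cox(df, "grs")
    list(r2_max = r2, weights = cand, loghr = unname(fit$beta["grs"]),
         se = unname(fit$robust_se["grs"]), n_variants = nrow(cand))
  })
  entries <- Filter(Negate(is.null), entries)
  if (!length(entries)) {
    stop_validation("no candidate retained any variants at the given cutoff")
  }
  structure(entries, class = "candidate_grid")
}

#' Select the best candidate GRS from a grid
#'
#' Returns the entry with the largest-magnitude fitted log hazard ratio;
#' ties break toward the smaller `r2_max` (the sparser score).
#'
#' @param grid A `candidate_grid` from [build_candidate_grid()], or any
#'   list of entries carrying `r2_max`, `weights` and `loghr`.
#' @return The winning entry (list with `r2_max`, `weights`, `loghr`, ...).
#' @export
select_candidate <- function(grid) {
  if (!length(grid)) stop_validation("empty candidate grid")
  loghr <- vapply(grid, function(e) abs(e$loghr), numeric(1))
  r2 <- vapply(grid, function(e) e$r2_max, numeric(1))
  best <- order(-loghr, r2)[1L]
  grid[[best]]
}

#' Pairwise partial correlations between component scores
#'
#' For every unordered pair of standardised scores, regresses each score on
#' the other plus the covariates and averages the two slope coefficients
#' (both scores are standardised, so the slope is the partial Pearson
#' correlation up to estimation error). The upper-triangle tests are
#' BH-adjusted and the display order comes from average-linkage
#' hierarchical clustering of `1 - |r|`.
#'
#' @param scores Named list of K >= 2 standardised [score_vector()]s over
#'   the same samples.
#' @param covariates Optional data frame of per-sample adjustment
#'   covariates (same sample order as the scores).
#' @return List with `r` (K x K matrix, unit diagonal), `pvalues` and
#'   `qvalues` (upper-triangle matrices), `order` (leaf order), and
#'   `n_tests`.
#' @export
component_correlation <- function(scores, covariates = NULL) {
  K <- length(scores)
  if (K < 2L) stop_validation("need at least two scores")
  ids <- scores[[1L]]$sample_ids
  if (!all(vapply(scores, function(s) identical(s$sample_ids, ids),
                  logical(1)))) {
    stop_validation("all scores must cover the same samples in the same order")
  }
  S <- vapply(scores, function(s) {
    if (is.null(s$std)) stop_validation("scores must be standardised")
    s$std
  }, numeric(length(ids)))
  labels <- names(scores)
  if (is.null(labels)) labels <- paste0("GRS", seq_len(K))
  colnames(S) <- labels
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)

  r <- diag(1, K)
  pv <- matrix(NA_real_, K, K)
  slope <- function(y, x) {
    X <- if (is.null(Z)) cbind(1, x) else cbind(1, x, Z)
    fit <- lm.fit(X, y)
    b <- fit$coefficients[2L]
    dfres <- length(y) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / dfres
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[2L, 2L])
    c(b, 2 * stats::pt(-abs(b / se), dfres))
  }
  for (a in seq_len(K - 1L)) {
    for (b in (a + 1L):K) {
      ab <- slope(S[, a], S[, b])
      ba <- slope(S[, b], S[, a])
      r[a, b] <- r[b, a] <- (ab[1L] + ba[1L]) / 2
      pv[a, b] <- ab[2L]
    }
  }
  dimnames(r) <- list(labels, labels)
  qv <- pv
  qv[upper.tri(qv)] <- bh_fdr(pv[upper.tri(pv)])
  hc <- hclust(as.dist(1 - abs(r)), method = "average")
  list(r = r, pvalues = pv, qvalues = qv, order = hc$order,
       labels = labels[hc$order], n_tests = K * (K - 1L) / 2L)
}
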