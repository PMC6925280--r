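# shared fixtures and independent brute-force oracles

toy_variants <- function(m, chrom = "1", spacing = 1000L) {
  data.frame(chrom = chrom, pos = spacing * seq_len(m),
             id = sprintf("rs%03d", seq_len(m)),
             effect_allele = rep(c("A", "T", "A", "C"), length.out = m),
             other_allele = rep(c("G", "C", "C", "G"), length.out = m),
             stringsAsFactors = FALSE)
}

toy_geno <- function(dosages, variants = toy_variants(ncol(dosages))) {
  genotype_matrix(sprintf("S%03d", seq_len(nrow(dosages))), variants,
                  dosages)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  header <- c("CHR", "POS", "ID", "EA", "OA", "BETA", "SE", "P", "EAF",
              "INFO")
  present <- intersect(header, names(df))
  data.table::fwrite(df[present], path, sep = "\t")
  path
}

small_arch <- function(K = 2, m = 60, h2 = 0.3, corr = 0.5, seed = 1,
                       block = 6L, r = 0.5) {
  gc <- matrix(corr, K, K)
  diag(gc) <- 1
  architecture_spec(m, rep(block, m / block), within_block_r = r,
                    traits = data.frame(label = paste0("T", seq_len(K)),
                                        h2 = h2, causal_fraction = 0.5),
                    genetic_corr = gc, seed = seed)
}

# Gompertz cohort with a single standard-normal predictor
sim_score_cohort <- function(n, loghr, seed, baseline_rate = 2e-5,
                             followup_years = 15, strata = FALSE) {
  df <- data.frame(sample_id = sprintf("P%06d", seq_len(n)),
                   score = rnorm(n))
  if (strata) df$stratum <- sample(c("female", "male"), n, replace = TRUE)
  set.seed(seed)
  df$score <- rnorm(n)
  simulate_survival(df, loghr = c(score = loghr),
                    baseline_rate = baseline_rate,
                    followup_years = followup_years, seed = seed)
}

new_toy_sumstats <- function(p, beta = seq_along(p) / 10) {
  m <- length(p)
  df <- toy_variants(m)
  df$beta <- beta
  df$pvalue <- p
  df$eaf <- rep(0.3, m)
  structure(df, class = c("sumstats", "data.frame"))
}

# all permutations of 1..n (n small)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# step-up BH oracle, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q[ord] <- pmin(cummin_rev, 1)
  q
}

# exhaustive pair-count oracle for Harrell's C under left truncation:
# the earlier event must fall strictly inside the other's (entry, exit]
# window; tied event times are not compared; score ties count 0.5
cindex_oracle <- function(entry, exit, event, score) {
  n <- length(exit)
  conc <- disc <- tiedx <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (p in list(c(i, j), c(j, i))) {
        a <- p[1]; b <- p[2]
        if (event[a] == 1 && entry[b] < exit[a] && exit[a] <= exit[b] &&
            !(event[b] == 1 && exit[b] == exit[a])) {
          if (score[a] > score[b]) conc <- conc + 1
          else if (score[a] < score[b]) disc <- disc + 1
          else tiedx <- tiedx + 1
        }
      }
    }
  }
  list(c = (conc + 0.5 * tiedx) / (conc + disc + tiedx),
       n_pairs = conc + disc + tiedx)
}

# matrix-based greedy pruning oracle (independent of the package sweep)
prune_oracle <- function(geno, window_kb, r2_max) {
  v <- geno$variants
  m <- nrow(v)
  R2 <- suppressWarnings(cor(geno$dosages,
                             use = "pairwise.complete.obs"))^2
  kept <- integer(0)
  for (j in seq_len(m)) {
    close_kept <- kept[v$chrom[kept] == v$chrom[j] &
                         abs(v$pos[j] - v$pos[kept]) <= window_kb * 1000]
    viol <- any(!is.na(R2[close_kept, j]) & R2[close_kept, j] > r2_max)
    if (!viol) kept <- c(kept, j)
  }
  v$id[kept]
}
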