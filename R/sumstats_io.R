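#' Column mapping for summary-statistic files
#'
#' Maps the canonical internal column names onto the column headers of a
#' summary-statistic file. The defaults follow the common
#' `CHR POS ID EA OA BETA SE P EAF INFO` layout; override individual
#' entries for files using other headers.
#'
#' @param chrom,pos,id,effect_allele,other_allele,beta,se,pvalue,eaf,info
#'   Column header in the file holding each field. `se`, `eaf` and `info`
#'   may be `NA` when the file lacks them.
#' @return Named character vector usable as `column_map` in
#'   [read_sumstats()].
#' @export
sumstats_columns <- function(chrom = "CHR", pos = "POS", id = "ID",
                             effect_allele = "EA", other_allele = "OA",
                             beta = "BETA", se = "SE", pvalue = "P",
                             eaf = "EAF", info = "INFO") {
  c(chrom = chrom, pos = pos, id = id, effect_allele = effect_allele,
    other_allele = other_allele, beta = beta, se = se, pvalue = pvalue,
    eaf = eaf, info = info)
}

VALID_ALLELES <- c("A", "C", "G", "T")

# columns that must be present and coercible for a row to survive
.SUMSTATS_REQUIRED <- c("chrom", "pos", "id", "effect_allele",
                        "other_allele", "beta", "pvalue")

new_sumstats <- function(df, trait_label = NA_character_) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, trait_label = trait_label,
            class = c("sumstats", "data.frame"))
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated summary-statistic file, validates and coerces each
#' field, and drops rows that fail coercion (non-numeric effect size or
#' p-value, invalid alleles, p outside \[0,1\], non-positive SE). The number
#' of rejected rows is recorded in the `n_rejected` attribute and reported
#' via a message.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named vector from [sumstats_columns()] mapping internal
#'   names to file headers.
#' @param trait_label Optional label for the trait the GWAS measured.
#' @return A `sumstats` data frame with columns `chrom`, `pos`, `id`,
#'   `effect_allele`, `other_allele`, `beta`, and any of `se`, `pvalue`,
#'   `eaf`, `info` present in the file; attributes `trait_label` and
#'   `n_rejected`.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          trait_label = NA_character_) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  need <- .SUMSTATS_REQUIRED
  mapped <- column_map[need]
  if (anyNA(mapped)) {
    stop_format("column map lacks mandatory field(s): %s",
                paste(need[is.na(mapped)], collapse = ", "))
  }
  assert_columns(raw, unname(mapped), sprintf("summary-statistic file %s", path))

  out <- data.frame(
    chrom = as.character(raw[[column_map[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    id = as.character(raw[[column_map[["id"]]]]),
    effect_allele = toupper(raw[[column_map[["effect_allele"]]]]),
    other_allele = toupper(raw[[column_map[["other_allele"]]]]),
    beta = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    pvalue = suppressWarnings(as.numeric(raw[[column_map[["pvalue"]]]])),
    stringsAsFactors = FALSE
  )
  for (opt in c("se", "eaf", "info")) {
    colname <- column_map[[opt]]
    if (!is.na(colname) && colname %in% names(raw)) {
      out[[opt]] <- suppressWarnings(as.numeric(raw[[colname]]))
    }
  }

  keep <- !is.na(out$pos) & out$pos >= 1L &
    !is.na(out$beta) & is.finite(out$beta) &
    !is.na(out$pvalue) & out$pvalue >= 0 & out$pvalue <= 1 &
    out$effect_allele %in% VALID_ALLELES &
    out$other_allele %in% VALID_ALLELES &
    out$effect_allele != out$other_allele
  if ("se" %in% names(out)) keep <- keep & (is.na(out$se) | out$se > 0)
  n_rejected <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop_format("no valid rows in %s", path)

  key <- paste(out$chrom, out$pos, out$effect_allele, out$other_allele)
  if (anyDuplicated(key)) {
    stop_format("duplicate variant rows in %s (first: %s)",
                path, key[which(duplicated(key))[1L]])
  }
  if (n_rejected > 0L) {
    message(sprintf("read_sumstats: rejected %d malformed row(s) from %s",
                    n_rejected, basename(path)))
  }
  res <- new_sumstats(out, trait_label)
  attr(res, "n_rejected") <- n_rejected
  res
}

#' Variant QC filter specification
#'
#' @param info_min Minimum imputation INFO score in \[0,1\]; rows strictly
#'   below are removed.
#' @param maf_min Minimum minor-allele frequency in \[0,0.5\]; rows strictly
#'   below are removed.
#' @return A `qc_filter` list.
#' @export
qc_filter <- function(info_min = 0, maf_min = 0) {
  assert_number(info_min, "info_min", 0, 1)
  assert_number(maf_min, "maf_min", 0, 0.5)
  structure(list(info_min = info_min, maf_min = maf_min),
            class = "qc_filter")
}

#' Apply variant-level QC to a summary-statistic table
#'
#' Removes rows whose minor-allele frequency `min(eaf, 1 - eaf)` or
#' imputation INFO is strictly below the thresholds. Rows exactly at a
#' threshold are kept. Row order is preserved and the filter is idempotent.
#'
#' @param table A `sumstats` table (or any data frame with the canonical
#'   columns).
#' @param spec A [qc_filter()].
#' @return The filtered table, same class and attributes.
#' @export
apply_variant_qc <- function(table, spec) {
  if (!inherits(spec, "qc_filter")) spec <- do.call(qc_filter, as.list(spec))
  keep <- rep(TRUE, nrow(table))
  if (spec$maf_min > 0) {
    if (!"eaf" %in% names(table)) {
      stop_validation("MAF filtering requires an `eaf` column")
    }
    maf <- pmin(table$eaf, 1 - table$eaf)
    keep <- keep & !is.na(maf) & maf >= spec$maf_min
  }
  if (spec$info_min > 0) {
    if (!"info" %in% names(table)) {
      stop_validation("INFO filtering requires an `info` column")
    }
    keep <- keep & !is.na(table$info) & table$info >= spec$info_min
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(table)
  for (a in setdiff(names(attrs), c("row.names", "names"))) {
    attr(out, a) <- attrs[[a]]
  }
  out
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_strand_ambiguous <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize alleles against a reference variant frame
#'
#' Matches rows to reference variants by (chrom, pos) and reconciles
#' alleles: identical effect/other alleles pass unchanged; swapped alleles
#' flip the sign of the effect column (and complement `eaf` when present);
#' strand-complemented alleles are complemented first and then matched or
#' swapped. Strand-ambiguous variants (A/T, C/G) and rows that cannot be
#' reconciled or are absent from the reference are dropped and counted.
#'
#' @param table A `sumstats` table or weight table carrying `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and an effect column.
#' @param reference Data frame of reference variants with `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, unique by (chrom, pos).
#' @param effect_col Name of the signed effect column to flip on allele
#'   swap (default `"beta"`, use `"weight"` for weight tables).
#' @return The harmonized table expressed in the reference allele frame,
#'   with a `harmonization` attribute counting `matched`, `swapped`,
#'   `strand_flipped`, `ambiguous_dropped` and `unmatched_dropped` rows.
#' @export
harmonize_alleles <- function(table, reference, effect_col = "beta") {
  assert_columns(reference, c("chrom", "pos", "effect_allele", "other_allele"),
                 "reference")
  assert_columns(table, c("chrom", "pos", "effect_allele", "other_allele",
                          effect_col), "table")
  refkey <- paste(reference$chrom, reference$pos)
  if (anyDuplicated(refkey)) {
    stop_validation("reference variants must be unique by (chrom, pos)")
  }
  idx <- match(paste(table$chrom, table$pos), refkey)

  ea <- table$effect_allele
  oa <- table$other_allele
  rea <- reference$effect_allele[idx]
  roa <- reference$other_allele[idx]

  ambiguous <- is_strand_ambiguous(ea, oa)
  same <- !is.na(idx) & !ambiguous & ea == rea & oa == roa
  swapped <- !is.na(idx) & !ambiguous & ea == roa & oa == rea
  flip_same <- !is.na(idx) & !ambiguous & !same & !swapped &
    allele_complement(ea) == rea & allele_complement(oa) == roa
  flip_swap <- !is.na(idx) & !ambiguous & !same & !swapped &
    allele_complement(ea) == roa & allele_complement(oa) == rea
  keep <- same | swapped | flip_same | flip_swap

  counts <- c(matched = sum(same), swapped = sum(swapped | flip_swap),
              strand_flipped = sum(flip_same | flip_swap),
              ambiguous_dropped = sum(ambiguous & !is.na(idx)),
              unmatched_dropped = sum(!keep & !(ambiguous & !is.na(idx))))

  out <- table
  negate <- swapped | flip_swap
  out[[effect_col]][negate] <- -out[[effect_col]][negate]
  if ("eaf" %in% names(out)) out$eaf[negate] <- 1 - out$eaf[negate]
  out$effect_allele <- rea
  out$other_allele <- roa
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_label") <- attr(table, "trait_label")
  attr(out, "harmonization") <- counts
  if (inherits(table, "sumstats")) class(out) <- c("sumstats", "data.frame")
  out
}

#' Write / read a per-SNP weight table
#'
#' The on-disk layout is tab-separated with columns `ID`, `EA`, `WEIGHT`
#' (the layout of released metaGRS weight files), preceded by `CHR`, `POS`,
#' `OA` when genomic coordinates are available. Weights are written with
#' full double precision so that `read_snp_weights(write_snp_weights(x))`
#' is lossless.
#'
#' @param table Data frame with columns `id`, `effect_allele`, `weight` and
#'   optionally `chrom`, `pos`, `other_allele`.
#' @param path Output file path.
#' @return `write_snp_weights()` returns `path` invisibly;
#'   `read_snp_weights()` returns a `snp_weights` data frame.
#' @export
write_snp_weights <- function(table, path) {
  assert_columns(table, c("id", "effect_allele", "weight"), "weight table")
  if (any(!is.finite(table$weight))) {
    stop_validation("all weights must be finite")
  }
  has_coord <- all(c("chrom", "pos", "other_allele") %in% names(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (has_coord) {
    key <- paste(table$chrom, table$pos, table$effect_allele,
                 table$other_allele)
    if (anyDuplicated(key)) stop_validation("duplicate variant keys")
    writeLines("CHR\tPOS\tID\tEA\tOA\tWEIGHT", con)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%.17g", table$chrom,
                       as.integer(table$pos), table$id, table$effect_allele,
                       table$other_allele, table$weight), con)
  } else {
    if (anyDuplicated(paste(table$id, table$effect_allele))) {
      stop_validation("duplicate variant keys")
    }
    writeLines("ID\tEA\tWEIGHT", con)
    writeLines(sprintf("%s\t%s\t%.17g", table$id, table$effect_allele,
                       table$weight), con)
  }
  invisible(path)
}

#' @rdname write_snp_weights
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  assert_columns(raw, c("ID", "EA", "WEIGHT"), sprintf("weight file %s", path))
  out <- data.frame(id = as.character(raw$ID),
                    effect_allele = toupper(raw$EA),
                    weight = as.numeric(raw$WEIGHT),
                    stringsAsFactors = FALSE)
  if (all(c("CHR", "POS", "OA") %in% names(raw))) {
    out$chrom <- as.character(raw$CHR)
    out$pos <- as.integer(raw$POS)
    out$other_allele <- toupper(raw$OA)
    out <- out[, c("chrom", "pos", "id", "effect_allele", "other_allele",
                   "weight")]
    key <- paste(out$chrom, out$pos, out$effect_allele, out$other_allele)
  } else {
    key <- paste(out$id, out$effect_allele)
  }
  if (anyDuplicated(key)) {
    stop_format("duplicate variant keys in %s", path)
  }
  if (any(!is.finite(out$weight))) {
    stop_format("non-finite weight in %s", path)
  }
  structure(out, class = c("snp_weights", "data.frame"))
}
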