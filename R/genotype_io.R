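#' Construct a genotype dosage matrix container
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param variants Data frame with `chrom`, `pos`, `id`, `effect_allele`,
#'   `other_allele`; dosages count copies of `effect_allele`.
#' @param dosages Numeric matrix, `n_samples x n_variants`, values in
#'   \[0,2\] or `NA` for missing calls.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(sample_ids, variants, dosages) {
  assert_columns(variants, c("chrom", "pos", "id", "effect_allele",
                             "other_allele"), "variants")
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants)) {
    stop_format("dosage dimensions (%d x %d) do not match %d samples x %d variants",
                nrow(dosages), ncol(dosages), length(sample_ids), nrow(variants))
  }
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.na(dosages)) && (rng[1] < 0 || rng[2] > 2)) {
    stop_validation("dosages must lie in [0, 2] or be NA")
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(sample_ids = as.character(sample_ids),
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.1f%% missing)\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# ---- PLINK bed/bim/fam ------------------------------------------------------
# .bed is SNP-major: magic 0x6c 0x1b 0x01, then ceiling(n/4) bytes per
# variant, two bits per sample (LSB first): 00 hom A1, 01 missing, 10 het,
# 11 hom A2. We orient dosages as the count of A1, and declare A1 the
# effect allele.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read genotypes from PLINK bed/bim/fam or VCF
#'
#' Dosages are oriented as counts of the declared effect allele: for PLINK
#' input the A1 (fifth .bim column) allele; for VCF input the ALT allele.
#' Missing calls are preserved as `NA`.
#'
#' @param path For `"plink"`, the file-set prefix (with or without the
#'   `.bed` extension); for `"vcf"`, a VCF file path.
#' @param format Either `"plink"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf(path)
}

#' Write genotypes to PLINK bed/bim/fam or VCF
#'
#' @param geno A [genotype_matrix()].
#' @param path Output prefix (PLINK) or file path (VCF).
#' @inheritParams read_genotypes
#' @return The path/prefix, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") write_plink(geno, path) else write_vcf(geno, path)
}

write_plink <- function(geno, prefix) {
  fam <- data.frame(fid = geno$sample_ids, iid = geno$sample_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  bim <- data.frame(chrom = geno$variants$chrom, id = geno$variants$id,
                    cm = 0L, pos = geno$variants$pos,
                    a1 = geno$variants$effect_allele,
                    a2 = geno$variants$other_allele)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)

  n <- length(geno$sample_ids)
  m <- nrow(geno$variants)
  codes <- matrix(3L, nrow = n, ncol = m)  # 11 = hom A2 (dosage 0)
  d <- geno$dosages
  codes[!is.na(d) & d == 2] <- 0L          # 00 = hom A1
  codes[!is.na(d) & d == 1] <- 2L          # 10 = het
  codes[is.na(d)] <- 1L                    # 01 = missing
  if (any(!is.na(d) & d != round(d))) {
    stop_validation("PLINK output requires hard-call dosages in {0, 1, 2}")
  }
  pad <- (4L - n %% 4L) %% 4L
  codes_p <- rbind(codes, matrix(0L, nrow = pad, ncol = m))
  idx <- seq(1L, nrow(codes_p), by = 4L)
  bytes <- codes_p[idx, , drop = FALSE] +
    4L * codes_p[idx + 1L, , drop = FALSE] +
    16L * codes_p[idx + 2L, , drop = FALSE] +
    64L * codes_p[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_format("PLINK file(s) not found: %s", paste(missing, collapse = ", "))
  }
  fam <- data.table::fread(paths[3], header = FALSE, data.table = FALSE)
  bim <- data.table::fread(paths[2], header = FALSE, data.table = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_variant <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:3], .BED_MAGIC)) {
    stop_format("%s is not a SNP-major PLINK .bed file", paths[1])
  }
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_variant * m) {
    stop_format("%s is truncated or inconsistent with .bim/.fam (%d bytes, expected %d)",
                paths[1], length(body), bytes_per_variant * m)
  }
  ints <- as.integer(body)
  # unpack 2-bit codes, sample index fastest, LSB first
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bytes_per_variant, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # code 0,1,2,3 -> dosage of A1
  dosages <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  variants <- data.frame(chrom = as.character(bim[[1]]), pos = as.integer(bim[[4]]),
                         id = as.character(bim[[2]]),
                         effect_allele = toupper(bim[[5]]),
                         other_allele = toupper(bim[[6]]),
                         stringsAsFactors = FALSE)
  genotype_matrix(as.character(fam[[2]]), variants, dosages)
}

# ---- VCF --------------------------------------------------------------------

write_vcf <- function(geno, path) {
  d <- geno$dosages
  if (any(!is.na(d) & d != round(d))) {
    gt_field <- "DS"
    body <- matrix(sprintf("%.6g", d), nrow = nrow(d))
    body[is.na(d)] <- "."
  } else {
    gt_field <- "GT"
    body <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    body[!is.na(d) & d == 0] <- "0/0"
    body[!is.na(d) & d == 1] <- "0/1"
    body[!is.na(d) & d == 2] <- "1/1"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=metagrs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of ALT allele">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")),
             con)
  v <- geno$variants
  lines <- paste(v$chrom, v$pos, v$id, v$other_allele, v$effect_allele,
                 ".", "PASS", ".", gt_field, sep = "\t")
  sample_part <- apply(body, 2L, paste, collapse = "\t")
  writeLines(paste(lines, sample_part, sep = "\t"), con)
  invisible(path)
}

read_vcf <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_format("no variant records in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (is.null(gt) || all(is.na(gt))) {
    raw <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(raw)) stop_format("%s carries neither GT nor DS fields", path)
    alt_count <- function(x) {
      ifelse(is.na(x) | grepl("\\.", x),
             NA_real_,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a != "0"), numeric(1)))
    }
    gt <- matrix(alt_count(as.vector(raw)), nrow = nrow(raw),
                 dimnames = dimnames(raw))
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, effect_allele = toupper(fix$ALT),
                         other_allele = toupper(fix$REF),
                         stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), variants, t(gt))
}
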