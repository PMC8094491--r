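# PLINK 1 binary (bed/bim/fam) reader and writer.
#
# The .bed payload is SNP-major: for each variant, ceiling(n/4) bytes, two
# bits per sample starting at the low bits.  Two-bit codes: 00 homozygous
# A1/A1, 10 heterozygous, 11 homozygous A2/A2, 01 missing.  Dosages here
# count the A1 allele (bim column 5), which the package treats as the
# effect allele; missing calls are NA.

#' Read a PLINK bed/bim/fam triplet
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_panel()]; dosages count the bim A1 allele.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths)))
    abort(sprintf("missing PLINK files for prefix '%s'", prefix),
          class = "neotwas_format_error")
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    abort("not a PLINK .bed file (bad magic)", class = "neotwas_format_error")
  if (raw[3] != as.raw(0x01))
    abort("only SNP-major .bed supported", class = "neotwas_format_error")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m)
    abort("bed payload size inconsistent with bim/fam dimensions",
          class = "neotwas_format_error")
  payload <- raw[-(1:3)]
  # decode all two-bit fields at once
  bits <- matrix(as.integer(rawToBits(payload)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] + 2L * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * bpv)[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)  # A1 dosage per code
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  rownames(dos) <- as.character(fam$V2)
  variants <- tibble(
    id = bim$V2, chrom = as.character(bim$V1), pos = bim$V4,
    allele_effect = bim$V5, allele_other = bim$V6
  )
  genotype_panel(dos, variants, individual_ids = as.character(fam$V1))
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- nrow(panel$dosages)
  m <- ncol(panel$dosages)
  fam <- data.frame(panel$individual_ids, panel$sample_ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  v <- panel$variants
  bim <- data.frame(v$chrom, v$id, 0, v$pos, v$allele_effect, v$allele_other)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  code_of <- function(d) {
    out <- integer(length(d))            # dosage -> two-bit code
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2] <- 0L
    out[!is.na(d) & d == 1] <- 2L
    out[!is.na(d) & d == 0] <- 3L
    out
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bpv - n
  for (j in seq_len(m)) {
    codes <- c(code_of(panel$dosages[, j]), rep(0L, pad))
    bytes <- codes[seq(1, length(codes), 4)] +
      4L * codes[seq(2, length(codes), 4)] +
      16L * codes[seq(3, length(codes), 4)] +
      64L * codes[seq(4, length(codes), 4)]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Write a simulated cohort to disk
#'
#' Emits the file layout the pipeline consumes: PLINK genotypes (also the
#' LD reference), one expression TSV + covariate TSV per tissue, a sample
#' map, the gene annotation, the GWAS summary TSV, and the ground truth.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(cohort$panel, file.path(dir, "genotypes"))
  for (tissue in names(cohort$expression)) {
    es <- cohort$expression[[tissue]]
    write_tsv_matrix(es$values, file.path(dir, paste0("expression_", tissue, ".tsv")))
    write.table(es$covariates, file.path(dir, paste0("covariates_", tissue, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$gwas, file.path(dir, "gwas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_flat <- cohort$truth |>
    mutate(causal_local = map_chr(.data$causal_local, paste, collapse = ","),
           beta_std = map_chr(.data$beta_std,
                              \(b) paste(signif(b, 8), collapse = ",")))
  write.table(truth_flat, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a GWAS summary-statistic TSV
#'
#' Columns `id, chrom, pos, allele_effect, allele_other` plus any of
#' `beta, se, z, n`; allele columns are forced to character so a bare `T`
#' allele is never parsed as a logical.  `z` is recomputed from `beta/se`
#' when absent and cross-checked when present.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_gwas <- function(path) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             colClasses = c(id = "character",
                                            chrom = "character",
                                            allele_effect = "character",
                                            allele_other = "character")))
  if (is.null(df$z)) df$z <- df$beta / df$se
  if (!is.null(df$beta) && !is.null(df$se) &&
      any(abs(df$z - df$beta / df$se) > 1e-6))
    abort("z inconsistent with beta/se", class = "neotwas_format_error")
  if (any(df$allele_effect == df$allele_other))
    abort("effect and other allele identical", class = "neotwas_format_error")
  df
}

#' Read a gene annotation TSV (gene, chrom, tss)
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c(gene = "character",
                                      chrom = "character")))
}

write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
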