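#' Genotype panel container
#'
#' Holds a samples-by-variants dosage matrix (counts of the effect allele,
#' `NA` for missing calls) together with variant metadata.  The same object
#' doubles as the LD reference panel for association and refinement.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.  Row names are sample ids, column names
#'   variant ids.
#' @param variants tibble with columns `id`, `chrom`, `pos` (1-based),
#'   `allele_effect`, `allele_other`, and optionally `maf`, `missingness`
#'   (recomputed if absent).
#' @param individual_ids character vector mapping each row of `dosages` to an
#'   individual; defaults to the sample ids.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, individual_ids = rownames(dosages)) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  storage.mode(dosages) <- "double"
  variants <- as_tibble(variants)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- variants$id
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad) > 0) abort("dosages must lie in {0, 1, 2} or be NA")
  # positions must be non-decreasing within chromosome
  ok <- variants |>
    group_by(.data$chrom) |>
    summarise(sorted = !is.unsorted(.data$pos)) |>
    pull(.data$sorted)
  if (!all(ok)) abort("variant positions must be non-decreasing within chromosome")
  variants <- recompute_variant_stats(dosages, variants)
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = rownames(dosages),
         individual_ids = as.character(individual_ids)),
    class = "genotype_panel"
  )
}

recompute_variant_stats <- function(dosages, variants) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  variants$maf <- pmin(af, 1 - af)
  variants$missingness <- colMeans(is.na(dosages))
  variants
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (%d individuals)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$individual_ids))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by variant and/or sample index
#'
#' @param panel a [genotype_panel()].
#' @param variants integer or logical index into the variant columns.
#' @param samples integer or logical index into the sample rows.
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  d <- panel$dosages
  v <- panel$variants
  ind <- panel$individual_ids
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ind <- ind[samples]
  }
  genotype_panel(d, v, ind)
}

#' Expression set container
#'
#' One tissue's genes-by-samples expression matrix, its sample-level
#' covariates, and the sample-to-individual map that records the repeated-
#' measure design (several tissues of one individual share a genotype).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param covariates tibble with one row per sample; must contain
#'   `sample_id` and (for normalization) a `diagnosis` column.
#' @param sample_to_individual named character vector, sample id to
#'   individual id.
#' @param tissue single tissue label.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, covariates, sample_to_individual,
                           tissue = "tissue") {
  stopifnot(is.matrix(values))
  covariates <- as_tibble(covariates)
  if (anyDuplicated(colnames(values))) abort("sample ids must be unique")
  if (anyDuplicated(rownames(values))) abort("gene ids must be unique")
  if (!setequal(colnames(values), covariates$sample_id))
    abort("covariates must cover exactly the samples in `values`")
  missing_map <- setdiff(colnames(values), names(sample_to_individual))
  if (length(missing_map) > 0) abort("every sample must map to one individual")
  covariates <- covariates[match(colnames(values), covariates$sample_id), ]
  structure(
    list(values = values, covariates = covariates,
         sample_to_individual = sample_to_individual[colnames(values)],
         tissue = tissue),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> tissue=%s: %d genes x %d samples (%d individuals)\n",
              x$tissue, nrow(x$values), ncol(x$values),
              length(unique(x$sample_to_individual))))
  invisible(x)
}
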