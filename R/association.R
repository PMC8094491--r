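# Summary-statistic TWAS association, imputation and validation.

STRAND_AMBIGUOUS <- c("A_T", "T_A", "C_G", "G_C")

#' Harmonize weight, GWAS and LD-panel alleles
#'
#' Intersects the gene's weighted variants with the GWAS summary and the
#' LD panel (intersection ordered by the panel), flips the GWAS z/beta
#' where effect/other alleles are swapped relative to the weights, and
#' drops strand-ambiguous (A/T, C/G) variants and allele mismatches.
#'
#' @param weights a `weight_model` from [cross_validate_and_select()] /
#'   [train_weights()] (needs `$alleles` and `$weights`).
#' @param gwas GWAS summary tibble (`id, allele_effect, allele_other, z`,
#'   optionally `beta, se`).
#' @param ld_panel a [genotype_panel()] used as LD reference.
#' @return Tibble with one row per retained variant: `id, weight, z,
#'   panel_col, flipped`, ordered like the panel; zero rows when nothing
#'   overlaps.
#' @export
harmonize_alleles <- function(weights, gwas, ld_panel) {
  wa <- weights$alleles
  wa$weight <- weights$weights
  v <- ld_panel$variants
  keep <- v$id %in% wa$id & v$id %in% gwas$id
  v <- v[keep, ]
  if (nrow(v) == 0) return(tibble(id = character(0), weight = numeric(0),
                                  z = numeric(0), panel_col = integer(0),
                                  flipped = logical(0)))
  gw <- gwas[match(v$id, gwas$id), ]
  ww <- wa[match(v$id, wa$id), ]
  pair <- paste(ww$allele_effect, ww$allele_other, sep = "_")
  ambiguous <- pair %in% STRAND_AMBIGUOUS
  same <- gw$allele_effect == ww$allele_effect & gw$allele_other == ww$allele_other
  swapped <- gw$allele_effect == ww$allele_other & gw$allele_other == ww$allele_effect
  ok <- !ambiguous & (same | swapped)
  tibble(
    id = v$id[ok],
    weight = ww$weight[ok],
    z = ifelse(swapped[ok], -gw$z[ok], gw$z[ok]),
    panel_col = which(keep)[ok],
    flipped = swapped[ok]
  )
}

#' Impute the cis-genetic expression component
#'
#' `component = Z_std w` over the gene's harmonized variants, with dosages
#' standardized within the target panel.
#'
#' @param weights a `weight_model`.
#' @param panel target [genotype_panel()].
#' @return Named numeric vector (per panel sample) with attribute
#'   `"zero_variance"` flagging a degenerate component.
#' @export
impute_expression <- function(weights, panel) {
  idx <- match(weights$variant_ids, panel$variants$id)
  ok <- !is.na(idx)
  if (!any(ok)) abort("no weighted variant present in the panel")
  Z <- standardize_columns(impute_mean(panel$dosages[, idx[ok], drop = FALSE]))
  comp <- drop(Z %*% weights$weights[ok])
  names(comp) <- panel$sample_ids
  attr(comp, "zero_variance") <- sd(comp) == 0
  comp
}

#' TWAS association z-score from GWAS summary statistics
#'
#' `z_twas = w'z / sqrt(w' V w)` with `V` the (shrunk) LD matrix of the
#' harmonized variants; the p-value is two-sided normal.
#'
#' @param harmonized output of [harmonize_alleles()].
#' @param ld_panel the LD reference [genotype_panel()]; ignored when `V`
#'   is supplied.
#' @param shrink identity shrinkage weight applied to V (default 0.05).
#' @param V optional pre-computed LD matrix over the harmonized variants
#'   (used as given, without shrinkage).
#' @return One-row tibble `z_twas, p, n_snps_used`, or zero rows if the
#'   predictor is degenerate.
#' @export
twas_z <- function(harmonized, ld_panel, shrink = 0.05, V = NULL) {
  if (nrow(harmonized) == 0) return(tibble(z_twas = numeric(0),
                                           p = numeric(0),
                                           n_snps_used = integer(0)))
  if (is.null(V)) {
    Z <- standardize_columns(
      impute_mean(ld_panel$dosages[, harmonized$panel_col, drop = FALSE]))
    V <- ld_shrink(cor(Z), shrink)
  }
  w <- harmonized$weight
  denom <- drop(t(w) %*% V %*% w)
  if (denom <= 1e-12) return(tibble(z_twas = numeric(0), p = numeric(0),
                                    n_snps_used = integer(0)))
  z <- sum(w * harmonized$z) / sqrt(denom)
  tibble(z_twas = z, p = 2 * pnorm(-abs(z)), n_snps_used = nrow(harmonized))
}

#' Benjamini-Hochberg FDR with an explicit comparison count
#'
#' Step-up BH q-values; `m` fixes the number of comparisons corrected for
#' (the matched-comparison convention), defaulting to `length(p)`.
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of comparisons (>= length(p)).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= length(p))
  p.adjust(p, method = "BH", n = m)
}

#' Gene-level TWAS over a weight list
#'
#' Harmonizes, tests and FDR-corrects every trained gene against a GWAS.
#'
#' @param weight_list named list of `weight_model` (from
#'   [train_weights()]).
#' @param gwas GWAS summary tibble.
#' @param ld_panel LD reference [genotype_panel()].
#' @param m comparisons for the FDR correction (default: genes tested).
#' @return Tibble of class `twas_result`: `gene, z_twas, p, q,
#'   n_snps_used, best_model, cv_r2, h2`, sorted by input order.
#' @export
twas_associate <- function(weight_list, gwas, ld_panel, m = NULL) {
  rows <- imap(weight_list, function(wm, g) {
    h <- harmonize_alleles(wm, gwas, ld_panel)
    tz <- twas_z(h, ld_panel)
    if (nrow(tz) == 0) return(NULL)
    mutate(tz, gene = g, best_model = wm$model_name,
           cv_r2 = wm$cv_r2, h2 = wm$h2, .before = 1)
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res$q <- bh_fdr(res$p, m %||% nrow(res))
  class(res) <- c("twas_result", class(res))
  res
}

#' Validate imputed against observed expression (Kendall)
#'
#' Tie-corrected Kendall tau-b between each gene's imputed component and
#' its scaled observed expression across shared samples, with two-sided
#' p-values and BH q over the tested genes.
#'
#' @param imputed genes-by-samples matrix of imputed components.
#' @param observed an [expression_set()] (scaled).
#' @param m comparisons for the FDR correction (default: genes tested).
#' @return Tibble `gene, tau, p, q, n`.
#' @export
validate_imputation <- function(imputed, observed, m = NULL) {
  shared <- intersect(colnames(imputed), colnames(observed$values))
  if (length(shared) < 10) abort("need at least 10 shared samples")
  genes <- intersect(rownames(imputed), rownames(observed$values))
  res <- map(genes, function(g) {
    x <- imputed[g, shared]
    y <- observed$values[g, shared]
    if (sd(x) == 0 || sd(y) == 0) return(NULL)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    tibble(gene = g, tau = unname(ct$estimate),
           p = min(max(ct$p.value, 0), 1),  # exact p can underflow past 0
           n = length(shared))
  })
  out <- bind_rows(res)
  if (nrow(out) > 0) out$q <- bh_fdr(out$p, m %||% nrow(out))
  out
}

#' GWAS p-value enrichment across gene bins
#'
#' Assigns every GWAS variant to exactly one of three bins with precedence
#' weighted > unweighted > intergenic (a variant inside the cis-window of
#' both a weighted and an unweighted gene counts once, as weighted), then
#' runs one-sided Wilcoxon rank-sum tests for the weighted bin having
#' smaller p-values than each other bin.
#'
#' @param gwas GWAS summary tibble with `chrom, pos, z` (p computed from z
#'   unless a `p` column is present).
#' @param weighted_genes,unweighted_genes tibbles `gene, chrom, tss`.
#' @param flank window half-width (default 5e5, matching training).
#' @return List: `bins` (tibble id/bin/p), `tests` (tibble comparison,
#'   statistic, p_value), `counts`.
#' @export
gwas_bin_enrichment <- function(gwas, weighted_genes, unweighted_genes,
                                flank = 5e5) {
  p <- if ("p" %in% names(gwas)) gwas$p else 2 * pnorm(-abs(gwas$z))
  in_windows <- function(genes) {
    hit <- rep(FALSE, nrow(gwas))
    for (i in seq_len(nrow(genes))) {
      hit <- hit | (gwas$chrom == genes$chrom[i] &
                      abs(gwas$pos - genes$tss[i]) <= flank)
    }
    hit
  }
  w <- in_windows(weighted_genes)
  u <- !w & in_windows(unweighted_genes)
  bin <- case_when(w ~ "weighted", u ~ "unweighted", TRUE ~ "intergenic")
  test_vs <- function(other) {
    if (sum(bin == "weighted") == 0 || sum(bin == other) == 0)
      return(tibble(comparison = paste0("weighted_vs_", other),
                    statistic = NA_real_, p_value = NA_real_))
    wt <- suppressWarnings(wilcox.test(p[bin == "weighted"], p[bin == other],
                                       alternative = "less"))
    tibble(comparison = paste0("weighted_vs_", other),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(
    bins = tibble(id = gwas$id, bin = bin, p = p),
    tests = bind_rows(test_vs("unweighted"), test_vs("intergenic")),
    counts = table(bin)
  )
}
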