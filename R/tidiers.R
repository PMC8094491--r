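# broom-style tidy()/glance() methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained weight model
#'
#' One row per cis-variant with its weight, alleles and the chosen model.
#'
#' @param x a `weight_model`.
#' @param ... unused.
#' @return A tibble `gene, variant_id, allele_effect, allele_other,
#'   weight, model`.
#' @exportS3Method generics::tidy
tidy.weight_model <- function(x, ...) {
  tibble(gene = x$gene, variant_id = x$variant_ids,
         allele_effect = x$alleles$allele_effect,
         allele_other = x$alleles$allele_other,
         weight = x$weights, model = x$model_name)
}

#' One-row summary of a trained weight model
#'
#' @param x a `weight_model`.
#' @param ... unused.
#' @return A tibble `gene, model, cv_r2, cv_p, h2, n_snps, n_nonzero`.
#' @exportS3Method generics::glance
glance.weight_model <- function(x, ...) {
  tibble(gene = x$gene, model = x$model_name, cv_r2 = x$cv_r2,
         cv_p = x$cv_p, h2 = x$h2, n_snps = length(x$weights),
         n_nonzero = sum(x$weights != 0))
}

#' Tidy an ancestry result
#'
#' @param x an `ancestry_result` from [pca_cluster()].
#' @param ... unused.
#' @return A tibble: sample id, leading PCs and cluster label.
#' @exportS3Method generics::tidy
tidy.ancestry_result <- function(x, ...) {
  mutate(x$pcs, cluster = unname(x$cluster_labels[.data$sample_id]))
}

#' One-row summary of an ancestry result
#'
#' @param x an `ancestry_result`.
#' @param ... unused.
#' @return A tibble with component counts and the variance explained by
#'   the two leading PCs.
#' @exportS3Method generics::glance
glance.ancestry_result <- function(x, ...) {
  tibble(n_samples = nrow(x$pcs),
         n_components_used = length(x$retained_components),
         pc1_var = x$variance_explained[1],
         pc2_var = x$variance_explained[2],
         n_clusters = length(unique(x$cluster_labels)))
}

#' Tidy an expansion result
#'
#' @param x an `expansion_result` from [expand_gene_set()].
#' @param ... unused.
#' @return The mean partial-correlation tibble with inclusion flags.
#' @exportS3Method generics::tidy
tidy.expansion_result <- function(x, ...) {
  mutate(x$mean_partial_corr,
         included = .data$gene %in% x$included_genes,
         broad = .data$gene %in% x$broad_set,
         narrow = .data$gene %in% x$narrow_set)
}

#' One-row summary of an expansion result
#'
#' @param x an `expansion_result`.
#' @param ... unused.
#' @return A tibble of set sizes.
#' @exportS3Method generics::glance
glance.expansion_result <- function(x, ...) {
  tibble(target = x$target, sd_cutoff = x$sd_cutoff,
         n_included = length(x$included_genes),
         n_cis_coregulated = length(x$cis_coregulated),
         n_broad = length(x$broad_set), n_narrow = length(x$narrow_set))
}
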