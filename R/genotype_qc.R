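# Variant/sample QC, LD pruning, PCA and ancestry clustering.

#' Filter variants on minor allele frequency and missingness
#'
#' Thresholds follow the ancestry-analysis convention: keep variants with
#' MAF strictly above `maf_min`, missingness strictly below `miss_max`, and
#' MAF strictly below `maf_max` (the maximum-MAF cap removes variants whose
#' frequency is so balanced that array strand errors are undetectable).
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum missingness fraction (default 0.1).
#' @param maf_max maximum minor allele frequency (default 0.40).
#' @return A filtered `genotype_panel`; variant order preserved.
#' @export
filter_variants <- function(panel, maf_min = 0.01, miss_max = 0.1,
                            maf_max = 0.40) {
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            maf_max >= 0, maf_max <= 1)
  v <- panel$variants
  keep <- v$maf > maf_min & v$missingness < miss_max & v$maf < maf_max
  if (!any(keep)) warn("no variants pass the filters; returning empty panel")
  subset_panel(panel, variants = keep)
}

#' Greedy windowed LD pruning
#'
#' Sweeps each chromosome left to right; a variant is dropped when its
#' squared Pearson correlation with any already-retained variant within
#' `window_kb` kilobases exceeds `r2_max`.  Keeping the earlier (left)
#' variant on ties makes the procedure deterministic.  Missing dosages are
#' mean-imputed for the correlation only.
#'
#' @param panel a [genotype_panel()].
#' @param window_kb window width in kb (default 50).
#' @param step_kb nominal step in kb (kept for interface compatibility; the
#'   sweep is per-variant, which is equivalent to the smallest step).
#' @param r2_max maximum allowed pairwise r-squared (default 0.2).
#' @return Integer vector of retained variant indices into `panel`.
#' @export
ld_prune <- function(panel, window_kb = 50, step_kb = 5, r2_max = 0.2) {
  v <- panel$variants
  X <- impute_mean(panel$dosages)
  keep <- integer(0)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    kept <- integer(0)
    for (j in idx) {
      near <- kept[v$pos[kept] >= v$pos[j] - window_kb * 1000]
      drop <- FALSE
      if (length(near) > 0) {
        sj <- sd(X[, j])
        if (sj == 0) {
          drop <- FALSE  # monomorphic: uncorrelated with everything
        } else {
          r <- suppressWarnings(cor(X[, j], X[, near, drop = FALSE]))
          r[is.na(r)] <- 0
          drop <- any(r^2 > r2_max)
        }
      }
      if (!drop) kept <- c(kept, j)
    }
    keep <- c(keep, kept)
  }
  sort(keep)
}

impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' PCA and ancestry clustering of genotype profiles
#'
#' Runs PCA on column-standardized dosages (missing calls mean-imputed for
#' the PCA only), keeps every component explaining more than `var_threshold`
#' of the variance, and clusters samples on those components with k-means
#' (k-means++ seeding under `seed`, so the result is reproducible).
#'
#' @param panel a [genotype_panel()], ideally LD-pruned.
#' @param var_threshold keep PCs explaining more than this fraction of
#'   variance (default 0.01).
#' @param n_clusters number of clusters k (default 8).
#' @param seed seed for the k-means++ initialization.
#' @return List of class `ancestry_result`: `pcs` (tibble sample_id + PCs),
#'   `variance_explained`, `cluster_labels` (named integer vector in
#'   `1..n_clusters`), `retained_components`.
#' @export
pca_cluster <- function(panel, var_threshold = 0.01, n_clusters = 8,
                        seed = 1L) {
  X <- impute_mean(panel$dosages)
  if (nrow(X) < n_clusters) abort("need at least n_clusters samples")
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  use <- which(ve > var_threshold)
  if (length(use) < 1) {
    warn("no component exceeds the variance threshold; falling back to PC1")
    use <- 1L
  }
  scores <- pc$x[, use, drop = FALSE]
  centers <- kmeanspp_centers(scores, n_clusters, seed)
  km <- kmeans(scores, centers = centers, iter.max = 100)
  labels <- setNames(km$cluster, panel$sample_ids)
  structure(
    list(
      pcs = tibble(sample_id = panel$sample_ids,
                   as_tibble(pc$x[, seq_len(min(10, ncol(pc$x))), drop = FALSE])),
      variance_explained = ve,
      cluster_labels = labels,
      retained_components = use
    ),
    class = "ancestry_result"
  )
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_centers <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (i in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    centers[i + 1, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[i + 1, ], "-")^2))
  }
  centers
}

#' Select samples in clusters anchored by reference individuals
#'
#' Returns every sample whose cluster contains at least one of the supplied
#' reference ids (e.g. 1000 Genomes CEU individuals), mirroring the
#' reference-anchored definition of the ancestry-matched analysis set.
#'
#' @param result an `ancestry_result` from [pca_cluster()].
#' @param reference_ids sample ids of the reference individuals.
#' @return Character vector of retained sample ids.
#' @export
select_reference_clusters <- function(result, reference_ids) {
  labels <- result$cluster_labels
  ref <- intersect(reference_ids, names(labels))
  anchored <- unique(labels[ref])
  if (length(anchored) == 0) {
    warn("no cluster contains a reference individual; returning empty set")
    return(character(0))
  }
  names(labels)[labels %in% anchored]
}
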