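# Co-expression gene-set expansion and cell-type enrichment.

#' Bootstrapped partial correlation of a target gene to all others
#'
#' Per tissue and bootstrap replicate (individuals resampled with
#' replacement, all of an individual's samples moving together), a sparse
#' elastic-net regression of the target gene's expression on all other
#' genes selects a support, which is refit by OLS; each selected gene's
#' partial correlation is `t / sqrt(t^2 + df)` from that refit, unselected
#' genes score 0.  Values are averaged over bootstraps within tissue and
#' then across tissues.  Deterministic under `seed`.
#'
#' @param target gene id.
#' @param expression list of (prepared) [expression_set()].
#' @param B bootstrap replicates per tissue (default 100).
#' @param seed integer seed.
#' @return Tibble `gene, mean_partial_corr`, excluding the target, sorted
#'   by decreasing absolute value.
#' @export
bootstrap_partial_regression <- function(target, expression, B = 100,
                                         seed = 1L) {
  set.seed(seed)
  per_tissue <- list()
  for (tissue in names(expression)) {
    es <- expression[[tissue]]
    if (!target %in% rownames(es$values)) next
    Y <- es$values
    others <- setdiff(rownames(Y), target)
    X <- t(Y[others, , drop = FALSE])
    y <- Y[target, ]
    inds <- unique(es$sample_to_individual)
    samples_of <- split(colnames(Y), es$sample_to_individual[colnames(Y)])
    acc <- matrix(0, B, length(others), dimnames = list(NULL, others))
    for (b in seq_len(B)) {
      boot_inds <- sample(inds, length(inds), replace = TRUE)
      rows <- unlist(samples_of[boot_inds], use.names = FALSE)
      acc[b, ] <- sparse_partial_corr(X[rows, , drop = FALSE], y[rows])
    }
    per_tissue[[tissue]] <- colMeans(acc)
  }
  if (length(per_tissue) == 0)
    abort(sprintf("gene '%s' absent from every tissue", target))
  mean_vec <- Reduce(`+`, per_tissue) / length(per_tissue)
  tibble(gene = names(mean_vec), mean_partial_corr = unname(mean_vec)) |>
    arrange(desc(abs(.data$mean_partial_corr)))
}

# elastic-net support selection + OLS refit partial correlations
sparse_partial_corr <- function(X, y) {
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  sds <- apply(X, 2, sd)
  usable <- sds > 0
  if (sd(y) == 0 || !any(usable)) return(out)
  fit <- tryCatch(
    glmnet::glmnet(X[, usable, drop = FALSE], y, alpha = 0.5,
                   nlambda = 30, standardize = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  # smallest lambda keeping the support comfortably below n for the refit
  nmax <- max(floor(nrow(X) / 2), 1)
  k <- fit$df
  ok <- which(k > 0 & k <= nmax)
  if (length(ok) == 0) return(out)
  s <- fit$lambda[max(ok)]
  w <- as.vector(coef(fit, s = s))[-1]
  sel <- which(w != 0)
  if (length(sel) == 0) return(out)
  Xs <- X[, usable, drop = FALSE][, sel, drop = FALSE]
  df <- nrow(Xs) - ncol(Xs) - 1
  if (df < 3) return(out)
  ls <- lm(y ~ Xs)
  tv <- suppressWarnings(summary(ls))$coefficients[-1, "t value"]
  pc <- tv / sqrt(tv^2 + df)
  out[colnames(X)[usable][sel][seq_along(pc)]] <- pc
  out
}

#' Genes co-regulated with the target inside its cis-window
#'
#' Returns cis-window genes whose mean (partial) correlation with the
#' target exceeds the threshold: candidates for seeding the expansion
#' alongside the target (the locus-neighbour check).
#'
#' @param target gene id.
#' @param mean_corr tibble `gene, mean_partial_corr` from
#'   [bootstrap_partial_regression()].
#' @param annotation tibble `gene, chrom, tss`.
#' @param flank window half-width (default 5e5).
#' @param threshold inclusion threshold (default 0.1, strict inequality).
#' @return Character vector of cis co-regulated gene ids.
#' @export
cis_coregulation_check <- function(target, mean_corr, annotation,
                                   flank = 5e5, threshold = 0.1) {
  a <- annotation[annotation$gene == target, ]
  if (nrow(a) == 0) abort("target not annotated")
  cis_genes <- annotation$gene[annotation$chrom == a$chrom &
                                 abs(annotation$tss - a$tss) <= flank &
                                 annotation$gene != target]
  hits <- mean_corr$gene %in% cis_genes &
    mean_corr$mean_partial_corr > threshold
  mean_corr$gene[hits]
}

#' Standard-deviation cutoff inclusion
#'
#' Includes genes whose mean partial correlation lies more than `s`
#' standard deviations from the vector's mean (which is centered near
#' zero); smaller `s` gives nested supersets.
#'
#' @param mean_corr tibble `gene, mean_partial_corr`.
#' @param s SD multiplier (default 1.3).
#' @return Character vector of included gene ids.
#' @export
sd_cutoff_inclusion <- function(mean_corr, s = 1.3) {
  stopifnot(s > 0)
  v <- mean_corr$mean_partial_corr
  sdev <- sd(v)
  if (!is.finite(sdev) || sdev == 0) return(character(0))
  mean_corr$gene[abs(v - mean(v)) > s * sdev]
}

#' Elbow diagnostic for the SD cutoff
#'
#' Set size as a function of the SD multiplier, for choosing `s` per seed
#' gene by eye.
#'
#' @param mean_corr tibble `gene, mean_partial_corr`.
#' @param s_grid multipliers to evaluate.
#' @return Tibble `s, set_size`.
#' @export
sd_cutoff_elbow <- function(mean_corr, s_grid = seq(0.1, 3, by = 0.1)) {
  tibble(s = s_grid,
         set_size = vapply(s_grid,
                           \(s) length(sd_cutoff_inclusion(mean_corr, s)),
                           integer(1)))
}

#' Expand a seed gene set through an interaction network
#'
#' Extracts every edge touching the seed set from an undirected,
#' deduplicated edge list and counts how often each non-seed gene appears
#' across those edges: `broad` keeps genes appearing more than once,
#' `narrow` more than twice; both are filtered to the expressed universe.
#'
#' @param seed_set character vector (e.g. top-50 partial-regression genes
#'   plus the target).
#' @param edges tibble/data frame with two columns of gene ids.
#' @param expressed_universe genes expressed in at least one tissue.
#' @return List `broad_set`, `narrow_set` (narrow is a subset of broad),
#'   and `counts` (tibble gene/n).
#' @export
network_expand <- function(seed_set, edges, expressed_universe) {
  e <- tibble(a = as.character(edges[[1]]), b = as.character(edges[[2]]))
  e <- distinct(mutate(e, lo = pmin(.data$a, .data$b),
                       hi = pmax(.data$a, .data$b)), .data$lo, .data$hi)
  touch <- e$lo %in% seed_set | e$hi %in% seed_set
  inc <- c(e$lo[touch], e$hi[touch])
  inc <- inc[!inc %in% seed_set]
  cnt <- table(inc)
  counts <- tibble(gene = as.character(names(cnt) %||% character(0)),
                   n = as.integer(cnt))
  broad <- counts$gene[counts$n > 1]
  narrow <- counts$gene[counts$n > 2]
  list(broad_set = intersect(broad, expressed_universe),
       narrow_set = intersect(narrow, expressed_universe),
       counts = counts)
}

#' Marker / term over-representation by exact binomial test
#'
#' For each marker (or process-term) set: odds ratio = observed percent
#' overlap divided by expected percent
#' (`(k/n) / (|marker|/|universe|)`) and a two-sided exact binomial
#' p-value for `k` successes in `n = |set (in universe)|` trials at
#' `p0 = |marker (in universe)| / |universe|`; BH correction over the
#' marker sets tested.  Genes outside the universe are dropped.
#'
#' @param set gene list to test.
#' @param markers tibble with columns `set_id, gene` (two-column TSV
#'   convention).
#' @param universe background gene list (expressed-gene universe).
#' @return Tibble `set_id, overlap, set_size, marker_size, odds_ratio, p,
#'   q, zero_overlap`.
#' @export
marker_enrichment <- function(set, markers, universe) {
  set <- intersect(unique(set), universe)
  n <- length(set)
  if (n == 0) abort("empty test set after restriction to the universe")
  marker_sets <- split(markers$gene, markers$set_id)
  rows <- imap(marker_sets, function(mg, id) {
    mg <- intersect(unique(mg), universe)
    p0 <- length(mg) / length(universe)
    k <- length(intersect(set, mg))
    if (p0 == 0) return(NULL)
    bt <- binom.test(k, n, p0, alternative = "two.sided")
    tibble(set_id = id, overlap = k, set_size = n, marker_size = length(mg),
           odds_ratio = (k / n) / p0, p = bt$p.value, zero_overlap = k == 0)
  })
  out <- bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Full expansion of one associated gene
#'
#' Runs [bootstrap_partial_regression()], the cis co-regulation check, the
#' SD-cutoff inclusion, and the network expansion from the top-K genes.
#'
#' @inheritParams bootstrap_partial_regression
#' @param annotation tibble `gene, chrom, tss`.
#' @param edges interaction edge list (2 columns).
#' @param s SD multiplier (default 1.3).
#' @param top_k seed size for the network expansion (default 50).
#' @param flank cis-window half-width.
#' @return List of class `expansion_result`.
#' @export
expand_gene_set <- function(target, expression, annotation, edges,
                            B = 100, s = 1.3, top_k = 50, flank = 5e5,
                            seed = 1L) {
  mc <- bootstrap_partial_regression(target, expression, B = B, seed = seed)
  cis <- cis_coregulation_check(target, mc, annotation, flank = flank)
  included <- sd_cutoff_inclusion(mc, s = s)
  universe <- unique(unlist(lapply(expression, \(e) rownames(e$values))))
  seed_set <- unique(c(target, cis, head(mc$gene, top_k)))
  net <- network_expand(seed_set, edges, universe)
  structure(
    list(target = target, mean_partial_corr = mc, cis_coregulated = cis,
         sd_cutoff = s, included_genes = included, seed_set = seed_set,
         broad_set = net$broad_set, narrow_set = net$narrow_set,
         elbow = sd_cutoff_elbow(mc), universe = universe),
    class = "expansion_result"
  )
}
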