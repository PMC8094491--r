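# Weight training: group-aware folds, the four predictive models, and
# cross-validated model selection.

#' Assemble the multi-tissue training set
#'
#' Concatenates the (prepared) per-tissue expression sets over their common
#' genes and pairs every expression sample with its individual's genotype
#' row, so individuals profiled in several regions appear once per sample.
#'
#' @param expression list of [expression_set()] (already normalized/scaled).
#' @param panel a [genotype_panel()] with one row per individual.
#' @return List: `values` (genes x samples matrix), `panel` (sample-level
#'   `genotype_panel`, rows repeated per sample, `individual_ids` recording
#'   the owner), `sample_to_individual`.
#' @export
build_training_set <- function(expression, panel) {
  genes <- Reduce(intersect, lapply(expression, \(e) rownames(e$values)))
  values <- do.call(cbind, lapply(expression, \(e) e$values[genes, , drop = FALSE]))
  s2i <- do.call(c, lapply(expression, \(e) e$sample_to_individual))
  missing <- setdiff(unique(s2i), panel$sample_ids)
  if (length(missing) > 0)
    abort("expression individuals absent from the genotype panel")
  rows <- match(s2i, panel$sample_ids)
  dos <- panel$dosages[rows, , drop = FALSE]
  rownames(dos) <- colnames(values)
  sample_panel <- genotype_panel(dos, panel$variants,
                                 individual_ids = unname(s2i))
  attr(sample_panel, "layout") <- attr(panel, "layout")
  list(values = values, panel = sample_panel,
       sample_to_individual = setNames(unname(s2i), colnames(values)))
}

#' Group-aware cross-validation folds
#'
#' Greedy bin-packing of individuals into k folds: individuals are sorted
#' by descending sample count (ties shuffled under `seed`) and each is
#' assigned to the currently smallest fold, so all samples of an individual
#' share one fold and fold sizes stay maximally balanced.
#'
#' @param sample_to_individual named character vector (sample -> individual).
#' @param k number of folds (default 5).
#' @param seed seed for tie shuffling.
#' @return List of class `fold_assignment`: `sample_fold` (named integer),
#'   `individual_fold` (named integer), `k`.
#' @export
make_group_folds <- function(sample_to_individual, k = 5, seed = 1L) {
  inds <- unique(sample_to_individual)
  if (k < 2) abort("k must be at least 2")
  if (k > length(inds)) abort("more folds than individuals")
  counts <- table(sample_to_individual)[inds]
  set.seed(seed)
  ord <- order(-as.integer(counts), sample.int(length(inds)))
  fold_of <- integer(length(inds))
  names(fold_of) <- inds
  sizes <- numeric(k)
  for (i in ord) {
    f <- which.min(sizes)
    fold_of[i] <- f
    sizes[f] <- sizes[f] + counts[i]
  }
  structure(
    list(sample_fold = setNames(fold_of[sample_to_individual],
                                names(sample_to_individual)),
         individual_fold = fold_of, k = k),
    class = "fold_assignment"
  )
}

#' Single best marginal eQTL model (top1)
#'
#' One nonzero weight at the variant with the largest absolute marginal
#' correlation with expression; its value is the marginal OLS slope on
#' standardized data.  Ties go to the lowest variant index.
#'
#' @param X standardized cis-genotype matrix (samples x variants).
#' @param y scaled expression vector.
#' @return Weight vector of length `ncol(X)`.
#' @export
fit_top1 <- function(X, y) {
  r <- suppressWarnings(cor(X, y))
  r[is.na(r)] <- 0
  j <- which.max(abs(r) - seq_along(r) * 1e-12)  # lowest index wins exact ties
  w <- numeric(ncol(X))
  w[j] <- sum(X[, j] * y) / sum(X[, j]^2)
  w
}

#' BLUP (ridge) weights
#'
#' `w = (X'X + m (1 - h2)/h2 I)^-1 X'y` on standardized genotypes with m
#' the number of cis-variants: the best linear unbiased predictor under the
#' infinitesimal model with the shrinkage set by the heritability estimate.
#'
#' @inheritParams fit_top1
#' @param h2 cis-heritability in (0, 1).
#' @return Weight vector of length `ncol(X)`.
#' @export
fit_blup <- function(X, y, h2) {
  if (h2 <= 0 || h2 >= 1) abort("h2 must be in (0, 1) for BLUP")
  m <- ncol(X)
  A <- crossprod(X) + diag(m * (1 - h2) / h2, m)
  drop(solve(A, crossprod(X, y)))
}

#' Lasso / elastic-net weights with group-aware inner tuning
#'
#' Coordinate-descent fit (glmnet); the penalty is chosen on an inner grid
#' by cross-validation over the SAME individual-grouped folds used for the
#' outer loop, so repeated samples of one individual never leak across the
#' tuning split.  Elastic-net mixing is fixed at 0.5.
#'
#' @inheritParams fit_top1
#' @param model_name `"lasso"` or `"enet"`.
#' @param folds a `fold_assignment` over the rows of `X` (its
#'   `sample_fold` must be ordered like `rownames(X)`/`y`).
#' @return Weight vector of length `ncol(X)` (may be all zero).
#' @export
fit_lasso_enet <- function(X, y, model_name = c("lasso", "enet"), folds) {
  model_name <- match.arg(model_name)
  alpha <- if (model_name == "lasso") 1 else 0.5
  if (ncol(X) < 2) return(fit_top1(X, y))
  foldid <- as.integer(folds$sample_fold)
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-11)
  w <- as.vector(coef(cv, s = "lambda.min"))[-1]
  attr(w, "lambda") <- cv$lambda.min
  w
}

fit_model_weights <- function(model, X, y, h2, folds) {
  switch(model,
         top1 = fit_top1(X, y),
         blup = fit_blup(X, y, min(max(h2, 1e-4), 1 - 1e-4)),
         lasso = fit_lasso_enet(X, y, "lasso", folds),
         enet = fit_lasso_enet(X, y, "enet", folds),
         abort(paste("unknown model", model)))
}

subset_folds <- function(folds, keep) {
  sf <- folds$sample_fold[keep]
  # renumber folds 1..k' so glmnet foldid is contiguous
  lv <- sort(unique(sf))
  structure(list(sample_fold = setNames(match(sf, lv), names(sf)),
                 individual_fold = NULL, k = length(lv)),
            class = "fold_assignment")
}

#' Cross-validate the model set and select the best model for a gene
#'
#' For each candidate model, out-of-fold predictions are assembled over the
#' k grouped folds and scored by the signed squared correlation with the
#' observed expression (`cv_r2 = sign(r) r^2`; a constant prediction scores
#' 0).  The significance `cv_p` is the two-sided correlation test with the
#' number of *individuals* — not samples — as the effective n, respecting
#' the repeated-measure design.  Final weights are refit on all data under
#' the winning model; genes whose best `cv_r2` is not positive are flagged
#' `dropped` (their imputed component would carry no variance).
#'
#' @param X standardized cis-genotype matrix (samples x variants).
#' @param y scaled expression vector.
#' @param folds `fold_assignment` over the samples of `X`.
#' @param h2 heritability estimate for the BLUP shrinkage.
#' @param models candidate model names (default all four).
#' @return List of class `weight_model`: `gene` (NA here; set by callers),
#'   `model_name`, `weights`, `variant_ids`, `cv_r2`, `cv_p`, `h2`,
#'   `cv_table` (per-model tibble), `dropped`.
#' @export
cross_validate_and_select <- function(X, y, folds, h2,
                                      models = c("top1", "blup", "lasso", "enet")) {
  stopifnot(nrow(X) == length(y))
  sf <- as.integer(folds$sample_fold)
  stopifnot(length(sf) == length(y))
  n_ind <- if (!is.null(folds$individual_fold))
    length(folds$individual_fold) else length(unique(sf))
  preds <- matrix(NA_real_, nrow(X), length(models),
                  dimnames = list(NULL, models))
  for (f in sort(unique(sf))) {
    test <- sf == f
    train <- !test
    inner <- subset_folds(folds, train)
    for (mod in models) {
      w <- tryCatch(fit_model_weights(mod, X[train, , drop = FALSE], y[train],
                                      h2, inner),
                    error = function(e) rep(0, ncol(X)))
      preds[test, mod] <- X[test, , drop = FALSE] %*% w
    }
  }
  score <- function(p) {
    if (sd(p) == 0) return(c(r2 = 0, p = 1))
    r <- cor(p, y)
    df <- max(n_ind - 2, 1)
    tt <- r * sqrt(df / max(1 - r^2, 1e-12))
    c(r2 = sign(r) * r^2, p = 2 * pt(-abs(tt), df))
  }
  sc <- t(apply(preds, 2, score))
  cv_table <- tibble(model = models, cv_r2 = sc[, "r2"], cv_p = sc[, "p"])
  best <- models[which.max(sc[, "r2"])]
  dropped <- max(sc[, "r2"]) <= 0
  w_final <- fit_model_weights(best, X, y, h2, folds)
  if (all(w_final == 0)) dropped <- TRUE
  structure(
    list(gene = NA_character_, model_name = best, weights = w_final,
         variant_ids = colnames(X),
         cv_r2 = unname(sc[best, "r2"]), cv_p = unname(sc[best, "p"]),
         h2 = h2, cv_table = cv_table, dropped = dropped),
    class = "weight_model"
  )
}

#' Train weights for every gene passing the heritability gate
#'
#' @param training output of [build_training_set()] with prepared
#'   expression.
#' @param annotation tibble `gene, chrom, tss`.
#' @param h2_estimates tibble from [estimate_cis_h2()].
#' @param genes genes to train (default: [heritability_gate()] at 0.01).
#' @param k folds (default 5); `seed` drives fold construction.
#' @param flank cis-window half-width.
#' @param models candidate model names.
#' @param seed integer seed.
#' @return List of `weight_model` objects (dropped genes excluded), named
#'   by gene; the per-gene weight tables are available via [tidy()].
#' @export
train_weights <- function(training, annotation, h2_estimates,
                          genes = NULL, k = 5, flank = 5e5,
                          models = c("top1", "blup", "lasso", "enet"),
                          seed = 1L) {
  if (is.null(genes)) genes <- heritability_gate(h2_estimates)
  folds <- make_group_folds(training$sample_to_individual, k = k, seed = seed)
  panel <- training$panel
  out <- list()
  for (g in genes) {
    ann <- annotation[annotation$gene == g, ]
    if (nrow(ann) == 0 || !g %in% rownames(training$values)) next
    win <- cis_window(panel, ann$chrom, ann$tss, flank)
    if (length(win) == 0) next
    X <- panel$dosages[, win, drop = FALSE]
    keep <- apply(X, 2, \(cc) !anyNA(cc) && sd(cc) > 0)
    if (!any(keep)) next
    Z <- standardize_columns(X[, keep, drop = FALSE])
    colnames(Z) <- panel$variants$id[win][keep]
    h2 <- h2_estimates$h2[match(g, h2_estimates$gene)]
    wm <- cross_validate_and_select(Z, training$values[g, ], folds, h2,
                                    models = models)
    wm$gene <- g
    wm$alleles <- panel$variants[win, c("id", "allele_effect", "allele_other")][keep, ]
    if (!wm$dropped) out[[g]] <- wm
  }
  out
}
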