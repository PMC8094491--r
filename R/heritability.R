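# Cis-heritability: GRM construction, single-component REML, LRT gate.

#' Cis-window of a gene
#'
#' Variants within `flank` bases of the TSS (1 Mb window centered on the
#' TSS by default, i.e. flank 500 kb each side).
#'
#' @param panel a [genotype_panel()].
#' @param chrom,tss gene chromosome and transcription start site (1-based).
#' @param flank window half-width in bases (default 5e5).
#' @return Integer vector of variant indices into `panel`.
#' @export
cis_window <- function(panel, chrom, tss, flank = 5e5) {
  v <- panel$variants
  which(v$chrom == chrom & v$pos >= tss - flank & v$pos <= tss + flank)
}

#' Genetic relatedness matrix from a cis-window
#'
#' `K = Z Z' / m` with `Z` the column-standardized dosages of the window's
#' m polymorphic variants; symmetric and positive semi-definite by
#' construction.  Missing dosages are mean-imputed (and that is logged via
#' a warning) — weight training itself uses complete cases only.
#'
#' @param panel a [genotype_panel()].
#' @param window integer vector of variant indices (from [cis_window()]).
#' @return The n-by-n relatedness matrix with attribute `"Z"` (the
#'   standardized dosage matrix, used for fast eigendecomposition) and
#'   `"m"` (number of variants).
#' @export
build_grm <- function(panel, window) {
  if (length(window) < 1) abort("empty cis-window")
  X <- panel$dosages[, window, drop = FALSE]
  if (anyNA(X)) {
    warn("mean-imputing missing dosages for the GRM")
    X <- impute_mean(X)
  }
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0)
    abort("all variants in the window are monomorphic",
          class = "neotwas_monomorphic_window")
  Z <- standardize_columns(X)
  m <- ncol(Z)
  K <- tcrossprod(Z) / m
  attr(K, "Z") <- Z
  attr(K, "m") <- m
  K
}

# Eigen-structure of K = ZZ'/m without forming the n x n decomposition when
# m << n: nonzero eigenvalues come from Z'Z/m, eigenvectors U = Z v /
# sqrt(m * lambda); the orthogonal complement has eigenvalue 0 and only its
# total squared projection of y is needed for the likelihood.
grm_eigen <- function(K) {
  Z <- attr(K, "Z")
  n <- nrow(K)
  if (!is.null(Z) && ncol(Z) < n) {
    m <- ncol(Z)
    e <- eigen(crossprod(Z) / m, symmetric = TRUE)
    pos <- e$values > 1e-10
    lam <- e$values[pos]
    U <- Z %*% e$vectors[, pos, drop = FALSE]
    U <- sweep(U, 2, sqrt(m * lam), "/")
    list(values = lam, vectors = U, low_rank = TRUE, n = n)
  } else {
    e <- eigen(K, symmetric = TRUE)
    list(values = pmax(e$values, 0), vectors = e$vectors, low_rank = FALSE,
         n = n)
  }
}

# Profile log-likelihood of y ~ N(0, s2 * (h2 K + (1-h2) I)) at h2, with the
# total variance s2 profiled out.  q = squared projections of y on the
# eigenvectors with eigenvalues lam; q0 = squared norm of the residual
# projection (eigenvalue 0), present only in the low-rank path.
profile_loglik <- function(h2, lam, q, q0, n) {
  d <- h2 * lam + (1 - h2)
  d0 <- 1 - h2
  if (any(d <= 0) || (q0 > 0 && d0 <= 0)) return(-Inf)
  ss <- sum(q / d) + if (q0 > 0) q0 / d0 else 0
  s2 <- ss / n
  logdet <- sum(log(d)) + (n - length(lam)) * log(d0)
  -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
}

#' REML estimate of cis-heritability
#'
#' Fits `y ~ N(0, sigma2_g K + sigma2_e I)` for a scaled expression vector
#' by a one-dimensional search on `h2 = sigma2_g / (sigma2_g + sigma2_e)`
#' over `[0, 1)`, with the total variance profiled out analytically using
#' the eigendecomposition of `K`.  The likelihood-ratio p-value against
#' `sigma2_g = 0` uses the boundary-corrected 50:50 mixture of a point mass
#' at zero and a 1-df chi-square.
#'
#' @param y scaled expression vector (mean 0).
#' @param K relatedness matrix from [build_grm()].
#' @param eig optional precomputed `grm_eigen(K)` (reused across genes that
#'   share a window).
#' @return One-row tibble: `h2, sigma2_g, sigma2_e, logl_alt, logl_null,
#'   p_value, converged`.
#' @export
reml_h2 <- function(y, K, eig = NULL) {
  n <- length(y)
  if (n != nrow(K)) abort("length(y) must match dim(K)")
  if (is.null(eig)) eig <- grm_eigen(K)
  proj <- crossprod(eig$vectors, y)
  q <- as.vector(proj)^2
  q0 <- if (eig$low_rank) max(sum(y^2) - sum(q), 0) else 0
  f <- function(h2) profile_loglik(h2, eig$values, q, q0, n)
  opt <- tryCatch(optimize(f, c(0, 0.9999), maximum = TRUE, tol = 1e-7),
                  error = function(e) NULL)
  ll0 <- f(0)
  if (is.null(opt)) {
    return(tibble(h2 = 0, sigma2_g = 0, sigma2_e = var(y),
                  logl_alt = ll0, logl_null = ll0, p_value = 1,
                  converged = FALSE))
  }
  h2 <- opt$maximum
  ll1 <- opt$objective
  if (ll0 >= ll1) { h2 <- 0; ll1 <- ll0 }
  lrt <- max(2 * (ll1 - ll0), 0)
  p <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  d <- h2 * eig$values + (1 - h2)
  ss <- sum(q / d) + if (q0 > 0) q0 / (1 - h2) else 0
  s2 <- ss / n
  tibble(h2 = h2, sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2,
         logl_alt = ll1, logl_null = ll0, p_value = p, converged = TRUE)
}

#' Estimate cis-heritability for every annotated gene
#'
#' @param panel a [genotype_panel()] restricted to the expression samples
#'   (one row per sample, repeated-measure rows allowed; typically the
#'   panel is indexed by individual and `y` columns map samples to
#'   individuals upstream).
#' @param values genes-by-samples scaled expression matrix whose columns
#'   align with `panel` rows.
#' @param annotation tibble `gene, chrom, tss`.
#' @param flank cis-window half-width (default 5e5).
#' @return Tibble: gene, n_snps, h2, sigma2_g, sigma2_e, logl_alt,
#'   logl_null, p_value, converged.
#' @export
estimate_cis_h2 <- function(panel, values, annotation, flank = 5e5) {
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation$gene[i]
    if (!g %in% rownames(values)) next
    win <- cis_window(panel, annotation$chrom[i], annotation$tss[i], flank)
    if (length(win) == 0) next
    K <- tryCatch(build_grm(panel, win), error = function(e) NULL)
    if (is.null(K)) next
    est <- reml_h2(values[g, ], K)
    out[[i]] <- mutate(est, gene = g, n_snps = attr(K, "m"), .before = 1)
  }
  bind_rows(out)
}

#' Heritability gate
#'
#' Genes whose cis-heritability LRT p-value is below the threshold (default
#' 0.01) pass on to weight training.
#'
#' @param estimates tibble from [estimate_cis_h2()] (needs `gene`,
#'   `p_value`).
#' @param p_threshold inclusion threshold (default 0.01).
#' @return Character vector of gene ids passing the gate.
#' @export
heritability_gate <- function(estimates, p_threshold = 0.01) {
  if (nrow(estimates) == 0) return(character(0))
  estimates |>
    filter(.data$p_value < p_threshold) |>
    pull(.data$gene)
}
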