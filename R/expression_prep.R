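# Covariate regression and scaling of expression, per tissue.

#' Iterative covariate regression
#'
#' Repeats until stable: for every remaining candidate covariate, fit the
#' per-gene simple linear model of current residual expression on that
#' covariate, summarize the covariate's significance across genes by the
#' median per-gene p-value, regress out (jointly) all covariates whose
#' median p is below `alpha`, and continue on the residuals.  Diagnosis is
#' always regressed in the first pass regardless of significance, as is
#' standard in TWAS/eQTL work where allelic risk is largely
#' condition-independent.  Constant covariates are dropped with a warning.
#'
#' @param es an [expression_set()].
#' @param candidates covariate column names to consider; default every
#'   numeric covariate except identifiers.
#' @param alpha significance level on the median p-value (default 0.05).
#' @param max_iter maximum number of passes (default 10).
#' @return The `expression_set` with residualized values; regressed
#'   covariates recorded in `attr(, "regressed")`.
#' @export
iterative_covariate_regression <- function(es, candidates = NULL,
                                           alpha = 0.05, max_iter = 10) {
  covs <- es$covariates
  if (is.null(candidates)) {
    candidates <- setdiff(names(covs)[vapply(covs, is.numeric, logical(1))],
                          c("sample_id", "individual_id"))
  }
  if (anyNA(covs[candidates])) abort("covariates must be complete")
  const <- candidates[vapply(candidates, \(cc) sd(covs[[cc]]) == 0, logical(1))]
  if (length(const) > 0) {
    warn(paste("dropping constant covariates:", paste(const, collapse = ", ")))
    candidates <- setdiff(candidates, const)
  }
  Y <- es$values
  regressed <- character(0)
  force_diag <- "diagnosis" %in% candidates
  for (it in seq_len(max_iter)) {
    remaining <- setdiff(candidates, regressed)
    if (length(remaining) == 0) break
    medp <- vapply(remaining, function(cc) {
      median(gene_wise_p(Y, covs[[cc]]))
    }, numeric(1))
    sel <- remaining[medp < alpha]
    if (it == 1 && force_diag) sel <- union(sel, "diagnosis")
    if (length(sel) == 0) break
    X <- cbind(1, as.matrix(covs[sel]))
    H <- X %*% solve(crossprod(X), t(X))
    Y <- Y - Y %*% H  # residualize each gene row on the selected covariates
    regressed <- c(regressed, sel)
  }
  out <- es
  out$values <- Y
  attr(out, "regressed") <- regressed
  out
}

# two-sided p-value of the slope in the per-gene simple regression of each
# row of Y on x, vectorized through the correlation t-test
gene_wise_p <- function(Y, x) {
  n <- ncol(Y)
  xs <- (x - mean(x)) / sd(x)
  ys <- Y - rowMeans(Y)
  denom <- sqrt(rowSums(ys^2)) * sqrt(n - 1)
  r <- as.vector(ys %*% xs) / denom
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Scale expression to per-gene mean 0, sd 1
#'
#' Standardizes each gene row using the sample standard deviation (n - 1).
#' Zero-variance genes are dropped with a message; this is the "pre-scaled
#' expression" contract that weight training assumes.
#'
#' @param es an [expression_set()].
#' @return The scaled `expression_set`.
#' @export
scale_expression <- function(es) {
  s <- apply(es$values, 1, sd)
  drop_genes <- which(s == 0 | !is.finite(s))
  out <- es
  if (length(drop_genes) > 0) {
    warn(sprintf("dropping %d zero-variance genes before scaling",
                 length(drop_genes)))
    out$values <- out$values[-drop_genes, , drop = FALSE]
    s <- s[-drop_genes]
  }
  out$values <- (out$values - rowMeans(out$values)) / s
  out
}

#' Normalize one tissue end to end
#'
#' Covariate regression followed by scaling; the combination used by the
#' pipeline's `normalize` stage.
#'
#' @inheritParams iterative_covariate_regression
#' @return A scaled, residualized `expression_set`.
#' @export
prepare_expression <- function(es, candidates = NULL, alpha = 0.05,
                               max_iter = 10) {
  scale_expression(
    iterative_covariate_regression(es, candidates, alpha, max_iter))
}
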