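# Small numeric helpers shared across modules.

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-standardize a dosage matrix (sample sd, n - 1).  Columns with zero
# variance become all-zero rather than NaN so downstream quadratic forms stay
# finite; callers that must exclude monomorphic variants check sd themselves.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- Inf
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}

# FUSION-style shrinkage of an LD/correlation matrix toward the identity
# before it enters any quadratic form or inverse.
ld_shrink <- function(V, lambda = 0.05) {
  V <- (1 - lambda) * V + lambda * diag(nrow(V))
  dimnames(V) <- NULL
  V
}

# Lower-tail standard bivariate normal probability P(X < h, Y < k) for
# correlation rho, by Gauss-Legendre quadrature of
# integral phi(x) Phi((k - rho x)/sqrt(1-rho^2)) over x in (-8.5, h).
bvn_lower <- function(h, k, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  gl <- gauss_legendre_48
  a <- -8.5
  if (h <= a) return(0)
  mid <- (h + a) / 2
  half <- (h - a) / 2
  x <- mid + half * gl$nodes
  s <- sqrt(1 - rho^2)
  half * sum(gl$weights * dnorm(x) * pnorm((k - rho * x) / s))
}

# 48-point Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre_48 <- local({
  n <- 48L
  # Golub-Welsch via symmetric tridiagonal eigenproblem
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
})

# Pearson correlation between two thresholded-Gaussian dosages with minor
# allele frequencies f1, f2 and latent haplotype correlation rho.
dosage_corr_from_latent <- function(rho, f1, f2) {
  p11 <- bvn_lower(qnorm(f1), qnorm(f2), rho)
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Latent correlation that realizes a target dosage correlation; capped at
# the maximum achievable for the given allele-frequency pair.
calibrate_latent_rho <- function(target, f1, f2) {
  if (target <= 0) return(0)
  hi <- 0.9999
  if (dosage_corr_from_latent(hi, f1, f2) <= target) return(hi)
  uniroot(function(r) dosage_corr_from_latent(r, f1, f2) - target,
          c(0, hi), tol = 1e-4)$root
}

# draw from N(0, Sigma) given a Cholesky-factorizable Sigma; ridge-regularize
# on failure (singular LD) with a warning.
rmvnorm_chol <- function(n, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    warn("LD matrix not positive definite; ridge-regularizing for the draw")
    R <- chol(Sigma + diag(1e-4, nrow(Sigma)))
  }
  matrix(rnorm(n * nrow(Sigma)), n) %*% R
}
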