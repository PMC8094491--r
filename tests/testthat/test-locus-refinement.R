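two_gene_models <- function(panel, wA, wB) {
  list(
    A = structure(list(gene = "A", model_name = "enet", weights = wA,
                       variant_ids = panel$variants$id, cv_r2 = 0.3,
                       cv_p = 1e-5, h2 = 0.3, dropped = FALSE,
                       alleles = panel$variants[, c("id", "allele_effect",
                                                    "allele_other")]),
                  class = "weight_model"),
    B = structure(list(gene = "B", model_name = "enet", weights = wB,
                       variant_ids = panel$variants$id, cv_r2 = 0.3,
                       cv_p = 1e-5, h2 = 0.3, dropped = FALSE,
                       alleles = panel$variants[, c("id", "allele_effect",
                                                    "allele_other")]),
                  class = "weight_model")
  )
}

test_that("predicted-expression correlation matches explicit imputation", {
  cfg <- sim_config(n_individuals = 600, n_loci = 1, n_variants_per_locus = 12,
                    ld_decay = 0.6, seed = 40)
  panel <- simulate_genotypes(cfg)
  set.seed(41)
  wA <- rnorm(12) * rbinom(12, 1, 0.5)
  wB <- rnorm(12) * rbinom(12, 1, 0.5)
  wl <- two_gene_models(panel, wA, wB)
  om <- predicted_expression_correlation(wl, panel, shrink = 0)
  compA <- impute_expression(wl$A, panel)
  compB <- impute_expression(wl$B, panel)
  expect_equal(om["A", "B"], cor(compA, compB), tolerance = 0.02)
  expect_equal(diag(om), c(A = 1, B = 1))

  # identical weights: correlation 1
  om1 <- predicted_expression_correlation(two_gene_models(panel, wA, wA),
                                          panel, shrink = 0)
  expect_equal(om1["A", "B"], 1, tolerance = 1e-10)

  # disjoint weights on unlinked loci: correlation ~ 0
  cfg2 <- sim_config(n_individuals = 2000, n_loci = 2, n_variants_per_locus = 6,
                     ld_decay = 0.9, seed = 42)
  p2 <- simulate_genotypes(cfg2)
  w1 <- c(rep(1, 6), rep(0, 6)); w2 <- c(rep(0, 6), rep(1, 6))
  om0 <- predicted_expression_correlation(two_gene_models(p2, w1, w2), p2,
                                          shrink = 0)
  expect_lt(abs(om0["A", "B"]), 0.1)
})

test_that("JCP classifies joint and marginal genes as the conditioning dictates", {
  # single gene: joint with unchanged z
  om1 <- matrix(1, 1, 1, dimnames = list("A", "A"))
  r1 <- jcp(c(A = 6), om1)
  expect_equal(r1$class, "joint")
  expect_equal(r1$z_joint, 6)

  # uncorrelated genes: both joint with unchanged z
  om2 <- diag(2); dimnames(om2) <- list(c("A", "B"), c("A", "B"))
  r2 <- jcp(c(A = 6, B = 5), om2)
  expect_equal(r2$class, c("joint", "joint"))
  expect_equal(r2$z_joint, c(6, 5), tolerance = 1e-10)

  # B driven purely by correlation with A: B conditional z collapses
  om3 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  r3 <- jcp(c(A = 8, B = 0.9 * 8), om3)
  expect_equal(r3$class[r3$gene == "A"], "joint")
  expect_equal(r3$class[r3$gene == "B"], "marginal")
  expect_lt(abs(r3$z_conditional[r3$gene == "B"]), 2)

  # input order invariance
  r3b <- jcp(c(B = 0.9 * 8, A = 8), om3[c(2, 1), c(2, 1)])
  expect_equal(r3b, r3)

  # conditioning is proper in the symmetric two-gene case
  zs <- c(A = 5, B = 4.8)
  omr <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  rr <- jcp(zs, omr)
  zc <- rr$z_conditional[rr$class == "marginal"]
  expect_true(all(abs(zc) <= abs(zs[rr$gene[rr$class == "marginal"]])))
})

test_that("SNP conditioning zeroes the selected gene's own signal only", {
  cfg <- sim_config(n_individuals = 800, n_loci = 1, n_variants_per_locus = 10,
                    ld_decay = 0.4, seed = 43)
  panel <- simulate_genotypes(cfg)
  w <- c(1, rep(0, 9))  # gene's predictor = SNP 1
  wl <- two_gene_models(panel, w, w)["A"]
  z_snp <- setNames(c(5, rnorm(9)), panel$variants$id)
  out <- conditional_snp_z(z_snp, wl, z_genes = 5, panel, shrink = 0)
  expect_lt(abs(out$z_conditional[1]), 1e-6)
  # a SNP uncorrelated with the predictor keeps its z (low LD at distance)
  far <- 10
  expect_lt(abs(out$z_conditional[far] - out$z[far]),
            abs(0.5 * out$z[far]) + 0.5)
})

test_that("SMR matches closed forms and the chi-square tail", {
  expect_equal(smr(2, 2)$smr_T, 2)
  out <- smr(5, 3)
  expect_equal(out$smr_T, 225 / 34, tolerance = 1e-12)
  expect_equal(out$smr_p, 0.0101, tolerance = 1e-2)
  expect_equal(out$smr_p, pchisq(225 / 34, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # z_e -> infinity limit: T -> z_g^2
  expect_equal(smr(1e6, 3)$smr_T, 9, tolerance = 1e-9)
  expect_error(smr(Inf, 1))
})

test_that("SMR p is calibrated against a Monte-Carlo null with a strong instrument", {
  set.seed(44)
  n <- 1e6
  z_e <- rnorm(n, mean = 50)  # asymptotic regime: T converges to z_g^2
  z_g <- rnorm(n)
  T_ <- z_e^2 * z_g^2 / (z_e^2 + z_g^2)
  for (thr in c(3.84, 6.63)) {
    emp <- mean(T_ > thr)
    nom <- pchisq(thr, 1, lower.tail = FALSE)
    se <- sqrt(nom * (1 - nom) / n)
    expect_lt(abs(emp - nom), 2 * se)
  }
})

test_that("colocalization posteriors normalize and rank hypotheses correctly", {
  set.seed(45)
  # null: everything flat -> H0 dominates
  n <- 50
  se <- rep(0.05, n)
  pp0 <- coloc_abf(rnorm(n, 0, 0.01), se, rnorm(n, 0, 0.01), se)
  expect_gt(pp0$pp_h0, 0.9)

  # random inputs still normalize
  pp <- coloc_abf(rnorm(n), se, rnorm(n), se)
  expect_equal(sum(unlist(pp)), 1, tolerance = 1e-9)

  # shared causal SNP: H4 top
  b <- numeric(n); b[25] <- 0.5
  noise <- function() rnorm(n, 0, 0.05)
  pp4 <- coloc_abf(b + noise(), se, 0.8 * b + noise(), se)
  expect_equal(which.max(unlist(pp4)), 5L, ignore_attr = TRUE)

  # distinct causal SNPs: H3 top
  b2 <- numeric(n); b2[5] <- 0.5
  pp3 <- coloc_abf(b + noise(), se, b2 + noise(), se)
  expect_equal(which.max(unlist(pp3)), 4L, ignore_attr = TRUE)

  expect_warning(deg <- coloc_abf(1, 0.1, 1, 0.1))
  expect_true(is.na(deg$pp_h0))
})
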