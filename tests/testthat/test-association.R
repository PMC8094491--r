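fake_weight_model <- function(ids, w, effect = "A", other = "G") {
  structure(list(gene = "g", model_name = "top1", weights = w,
                 variant_ids = ids, cv_r2 = 0.3, cv_p = 1e-4, h2 = 0.3,
                 dropped = FALSE,
                 alleles = tibble::tibble(id = ids, allele_effect = effect,
                                          allele_other = other)),
            class = "weight_model")
}

test_that("allele harmonization flips, drops ambiguity, ignores row order", {
  panel <- toy_panel(n = 50, m = 4, seed = 30)
  wm <- fake_weight_model(panel$variants$id, c(0.5, -0.2, 0.3, 0.1))
  gwas <- tibble::tibble(id = panel$variants$id, chrom = "chr1",
                         pos = panel$variants$pos,
                         allele_effect = c("A", "G", "A", "A"),
                         allele_other = c("G", "A", "G", "G"),
                         z = c(2, 1.5, -1, 0.5))
  h <- harmonize_alleles(wm, gwas, panel)
  expect_equal(h$z, c(2, -1.5, -1, 0.5))  # swapped SNP z negated
  expect_true(h$flipped[2])

  # involution: harmonizing pre-flipped input gives the same aligned z
  gwas_flipped <- gwas
  gwas_flipped$allele_effect[2] <- "A"; gwas_flipped$allele_other[2] <- "G"
  gwas_flipped$z[2] <- -gwas_flipped$z[2]
  expect_equal(harmonize_alleles(wm, gwas_flipped, panel)$z, h$z)

  # permuting GWAS rows changes nothing
  expect_equal(harmonize_alleles(wm, gwas[c(3, 1, 4, 2), ], panel), h)

  # strand-ambiguous SNP dropped
  wm_at <- fake_weight_model(panel$variants$id, c(0.5, -0.2, 0.3, 0.1),
                             effect = c("A", "A", "C", "A"),
                             other = c("T", "G", "G", "G"))
  h_at <- harmonize_alleles(wm_at, gwas, panel)
  expect_false(panel$variants$id[1] %in% h_at$id)
  expect_false(panel$variants$id[3] %in% h_at$id)
})

test_that("imputation is the weighted standardized dosage sum", {
  panel <- toy_panel(n = 80, m = 5, seed = 31)
  w <- fake_weight_model(panel$variants$id, c(0, 0, 0.7, 0, 0))
  comp <- impute_expression(w, panel)
  expect_equal(abs(cor(comp, panel$dosages[, 3])), 1, tolerance = 1e-12)
  expect_false(attr(comp, "zero_variance"))
  w0 <- fake_weight_model(panel$variants$id, rep(0, 5))
  expect_true(attr(impute_expression(w0, panel), "zero_variance"))
})

test_that("twas_z matches hand-computed quadratic forms and is scale invariant", {
  h <- tibble::tibble(id = c("a", "b"), weight = c(1, 1), z = c(2, 2),
                      panel_col = 1:2, flipped = FALSE)
  V <- matrix(c(1, 0.5, 0.5, 1), 2)
  out <- twas_z(h, V = V)
  expect_equal(out$z_twas, 4 / sqrt(3), tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-4 / sqrt(3)), tolerance = 1e-12)

  h10 <- h; h10$weight <- h$weight * 10
  expect_equal(twas_z(h10, V = V)$z_twas, out$z_twas, tolerance = 1e-12)

  h1 <- h[1, ]
  expect_equal(twas_z(h1, V = matrix(1))$z_twas, 2)
})

test_that("twas_z agrees with an individual-level regression oracle", {
  # simulate a GWAS cohort, compute per-SNP summary z, and compare the
  # summary-statistic TWAS z with the direct regression of the phenotype on
  # the imputed component
  set.seed(32)
  cfg <- sim_config(n_individuals = 5000, n_loci = 1, n_variants_per_locus = 10,
                    ld_decay = 0.5, h2_cis = 0.4, n_causal_eqtl = 2,
                    tissues = "A", tissue_assignment_probs = 1, seed = 33)
  panel <- simulate_genotypes(cfg)
  Z <- neotwas:::standardize_columns(panel$dosages)
  w <- c(0.4, 0.2, rep(0, 8))
  comp <- drop(Z %*% w)
  pheno <- 0.05 * scale(comp)[, 1] + rnorm(5000)
  z_snp <- vapply(1:10, function(j) {
    f <- lm(pheno ~ Z[, j])
    unname(coef(summary(f))[2, "t value"])
  }, numeric(1))
  gwas <- tibble::tibble(id = panel$variants$id, chrom = panel$variants$chrom,
                         pos = panel$variants$pos,
                         allele_effect = panel$variants$allele_effect,
                         allele_other = panel$variants$allele_other,
                         z = z_snp, beta = z_snp / sqrt(5000),
                         se = 1 / sqrt(5000), n = 5000)
  wm <- fake_weight_model(panel$variants$id, w,
                          effect = panel$variants$allele_effect,
                          other = panel$variants$allele_other)
  h <- harmonize_alleles(wm, gwas, panel)
  z_sum <- twas_z(h, panel, shrink = 0)$z_twas
  f <- lm(pheno ~ comp)
  z_direct <- unname(coef(summary(f))[2, "t value"])
  expect_lt(abs(z_sum - z_direct), 0.15)
})

test_that("BH correction matches the step-up oracle and the m convention", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(34)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  expect_equal(bh_fdr(p, m = 200), bh_oracle(p, m = 200), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("imputation validation reproduces brute-force Kendall tau", {
  set.seed(35)
  n <- 40
  imputed <- matrix(rnorm(2 * n), 2, dimnames = list(c("g1", "g2"),
                                                     paste0("s", 1:n)))
  observed_vals <- rbind(g1 = imputed["g1", ],
                         g2 = round(rnorm(n), 1))  # ties in g2
  covs <- tibble::tibble(sample_id = paste0("s", 1:n),
                         individual_id = paste0("i", 1:n), diagnosis = 0)
  es <- expression_set(observed_vals, covs,
                       setNames(covs$individual_id, covs$sample_id))
  out <- validate_imputation(imputed, es)
  expect_equal(out$tau[out$gene == "g1"], 1)
  expect_equal(out$tau[out$gene == "g2"],
               kendall_oracle(imputed["g2", ], observed_vals["g2", ]),
               tolerance = 1e-10)
  # sign flip negates tau
  out_neg <- validate_imputation(-imputed, es)
  expect_equal(out_neg$tau, -out$tau, tolerance = 1e-10)
  expect_error(validate_imputation(imputed[, 1:5],
                                   es), "shared samples")
})

test_that("GWAS bin enrichment applies precedence and detects shifts", {
  set.seed(36)
  n <- 3000
  gwas <- tibble::tibble(id = paste0("v", 1:n), chrom = "chr1",
                         pos = seq(1e5, 3e8, length.out = n),
                         z = rnorm(n))
  weighted <- tibble::tibble(gene = "gw", chrom = "chr1", tss = 5e7)
  unweighted <- tibble::tibble(gene = "gu", chrom = "chr1", tss = c(5.05e7, 1.5e8))
  out <- gwas_bin_enrichment(gwas, weighted, unweighted)
  # precedence: overlap of the two windows goes to 'weighted' exactly once
  both <- gwas$pos >= 5.05e7 - 5e5 & gwas$pos <= 5e7 + 5e5
  expect_true(all(out$bins$bin[both] == "weighted"))
  expect_equal(sum(out$counts), n)
  # identical distributions: both one-sided tests are non-significant
  expect_true(all(out$tests$p_value > 0.05))

  # inject smaller p-values in the weighted window -> significant shift
  gwas2 <- gwas
  inwin <- abs(gwas2$pos - 5e7) <= 5e5
  gwas2$z[inwin] <- rnorm(sum(inwin), mean = 3)
  out2 <- gwas_bin_enrichment(gwas2, weighted, unweighted)
  expect_true(all(out2$tests$p_value < 0.05))
})
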