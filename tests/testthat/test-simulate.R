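test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_individuals = 0), class = "neotwas_config_error")
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "neotwas_config_error")
  expect_error(sim_config(ld_decay = 1), class = "neotwas_config_error")
  expect_error(sim_config(n_causal_eqtl = 50, n_variants_per_locus = 10),
               class = "neotwas_config_error")
  expect_error(sim_config(h2_cis = 1, tissue_noise_sd = 0.5),
               class = "neotwas_config_error")
})

test_that("genotypes are dosages with the requested MAF and are seed-deterministic", {
  cfg <- sim_config(n_individuals = 300, n_loci = 4, n_variants_per_locus = 15,
                    maf_range = c(0.1, 0.4), seed = 7)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  # sampling error at n=300: allow a generous band around the target range
  expect_true(all(p1$variants$maf > 0.05 & p1$variants$maf < 0.47))
})

test_that("adjacent-variant dosage correlation tracks ld_decay", {
  cfg0 <- sim_config(n_individuals = 2000, n_loci = 2,
                     n_variants_per_locus = 10, ld_decay = 0, seed = 3)
  p0 <- simulate_genotypes(cfg0)
  r0 <- sapply(1:9, function(j) cor(p0$dosages[, j], p0$dosages[, j + 1]))
  expect_true(all(abs(r0) < 0.1))

  cfg8 <- sim_config(n_individuals = 5000, n_loci = 10,
                     n_variants_per_locus = 21, ld_decay = 0.8, seed = 5)
  p8 <- simulate_genotypes(cfg8)
  v <- p8$variants
  rs <- unlist(lapply(split(seq_len(nrow(v)), v$locus), function(ii) {
    sapply(seq_len(length(ii) - 1),
           function(j) cor(p8$dosages[, ii[j]], p8$dosages[, ii[j + 1]]))
  }))
  expect_length(rs, 200)
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("expression carries the stated heritability and a shared genetic component", {
  # h2 = 0: no genetic effect at all
  cfg0 <- sim_config(n_individuals = 200, n_loci = 3, n_variants_per_locus = 8,
                     h2_cis = 0, tissues = "A", tissue_assignment_probs = 1,
                     diagnosis_effect = 0, seed = 11)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(vapply(co0$truth$beta_std, function(b) all(b == 0), logical(1))))

  # h2 = 0.5, one causal variant: OLS R2 of expression on that variant ~ 0.5
  cfg5 <- sim_config(n_individuals = 1000, n_loci = 6, n_variants_per_locus = 8,
                     h2_cis = 0.5, n_causal_eqtl = 1, tissues = "A",
                     tissue_assignment_probs = 1, diagnosis_effect = 0,
                     prop_mediated = 0, seed = 12)
  co5 <- simulate_cohort(cfg5)
  r2 <- vapply(seq_len(6), function(l) {
    cs <- co5$truth$causal_local[[l]]
    col <- which(co5$panel$variants$locus == l)[cs]
    y <- co5$expression$A$values[l, ]
    x <- co5$panel$dosages[co5$expression$A$sample_to_individual, col]
    summary(lm(y ~ x))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.05)

  # noiseless case: genetic component identical across tissues of an individual
  cfg1 <- sim_config(n_individuals = 150, n_loci = 2, n_variants_per_locus = 6,
                     h2_cis = 1, tissues = c("A", "B"),
                     tissue_assignment_probs = c(1, 1), diagnosis_effect = 0,
                     seed = 13)
  co1 <- simulate_cohort(cfg1)
  a <- co1$expression$A; b <- co1$expression$B
  shared <- intersect(a$sample_to_individual, b$sample_to_individual)
  ia <- match(shared, a$sample_to_individual)
  ib <- match(shared, b$sample_to_individual)
  expect_equal(a$values[, ia], b$values[, ib], ignore_attr = TRUE)
})

test_that("realized heritability matches the target within 0.03 at n = 2000", {
  cfg <- sim_config(n_individuals = 2000, n_loci = 50,
                    n_variants_per_locus = 8, h2_cis = 0.3, tissues = "A",
                    tissue_assignment_probs = 1, seed = 21)
  panel <- simulate_genotypes(cfg)
  ex <- simulate_expression(panel, cfg)
  expect_lt(abs(mean(ex$truth$realized_h2) - 0.3), 0.03)
})

test_that("GWAS z-scores behave as the mediated-effect model dictates", {
  # null: fraction of loci with any |z| > 1.96 consistent with the MVN null
  cfg <- sim_config(n_individuals = 600, n_loci = 200, n_variants_per_locus = 1,
                    n_causal_eqtl = 1, mediation_effect = 0, prop_mediated = 0,
                    seed = 31)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$gwas), 200)
  # single-SNP loci: z ~ N(0,1), so ~5% beyond 1.96
  frac <- mean(abs(co$gwas$z) > 1.96)
  expect_lt(abs(frac - 0.05), 0.045)
  expect_equal(co$gwas$z, co$gwas$beta / co$gwas$se, tolerance = 1e-12)

  # sign contract: positive eQTL effect + positive mediation -> E[z] > 0
  cfgm <- sim_config(n_individuals = 600, n_loci = 40, n_variants_per_locus = 5,
                     n_causal_eqtl = 1, prop_mediated = 1,
                     mediation_effect = 0.2, seed = 32)
  com <- simulate_cohort(cfgm)
  zc <- vapply(seq_len(40), function(l) {
    cs <- com$truth$causal_local[[l]]
    b <- com$truth$beta_std[[l]][cs]
    idx <- which(com$gwas$chrom == com$annotation$chrom[l] &
                   com$gwas$id == sprintf("rs%d_%d", l, cs))
    sign(b) * com$gwas$z[idx]
  }, numeric(1))
  expect_gt(mean(zc), 2)
})

test_that("written cohorts round-trip through the PLINK reader", {
  cfg <- sim_config(n_individuals = 40, n_loci = 2, n_variants_per_locus = 6,
                    seed = 41)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_plink(file.path(dir, "genotypes"))
  expect_identical(unname(back$dosages), unname(co$panel$dosages))
  expect_equal(back$variants$pos, co$panel$variants$pos)
  expect_equal(back$variants$allele_effect, co$panel$variants$allele_effect)
})
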