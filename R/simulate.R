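# Synthetic cohort generator.
#
# The generator emulates the study design the pipeline was built for: a
# combined neocortical cohort where each individual carries one genotype
# profile but may contribute RNA-seq samples from several brain regions, a
# shared cis-genetic expression component of stated heritability, a binary
# diagnosis shifting expression, and GWAS summary statistics whose signal at
# a locus is mediated through expression.

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 790 individuals sampled across six neocortical regions with assignment
#' probabilities matching the observed region counts (481, 248, 34, 41, 34,
#' 50 of 790, so roughly 888 expression samples in expectation), moderate
#' cis-heritability (0.3) with three causal eQTL per gene, AR(1) LD with
#' decay 0.6, and a GWAS of 63,926 samples.
#'
#' @param n_individuals number of genotyped individuals.
#' @param n_variants_per_locus variants in each gene's cis locus.
#' @param n_loci number of gene loci (one gene per locus, loci unlinked).
#' @param maf_range range the per-variant minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param ld_decay target Pearson correlation between adjacent variant
#'   dosages, in `[0, 1)`; correlation decays as `ld_decay^|i-j|`.
#' @param h2_cis cis-heritability of expression in `[0, 1]`.
#' @param n_causal_eqtl causal cis-variants per gene.
#' @param tissues tissue labels.
#' @param tissue_assignment_probs per-tissue probability that an individual
#'   contributes a sample from that tissue.
#' @param mediation_effect trait effect per unit of (standardized) genetic
#'   expression component; 0 gives a null GWAS.
#' @param prop_mediated fraction of genes whose expression mediates trait
#'   risk (effect `mediation_effect`); the rest are GWAS-null.
#' @param gwas_n GWAS sample size used for the analytic z-score draw.
#' @param diagnosis_effect additive expression shift per case.
#' @param tissue_noise_sd sd of a tissue-level individual noise term added on
#'   top of the residual; must be 0 when `h2_cis = 1`.
#' @param covariate_effects named numeric vector of expression effects for
#'   generated nuisance covariates (`age`, `sex`, `pmi`, `batch`); default
#'   all zero.
#' @param seed integer seed driving all randomness of the generator.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 790,
                       n_variants_per_locus = 40,
                       n_loci = 50,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0.6,
                       h2_cis = 0.3,
                       n_causal_eqtl = 3,
                       tissues = c("DLPFC", "TCX", "PHG", "IFG", "STG", "FP"),
                       tissue_assignment_probs = c(481, 248, 34, 41, 34, 50) / 790,
                       mediation_effect = 0.1,
                       prop_mediated = 0.1,
                       gwas_n = 63926,
                       diagnosis_effect = 0.25,
                       tissue_noise_sd = 0,
                       covariate_effects = NULL,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants_per_locus = as.integer(n_variants_per_locus),
    n_loci = as.integer(n_loci),
    maf_range = as.numeric(maf_range),
    ld_decay = ld_decay, h2_cis = h2_cis,
    n_causal_eqtl = as.integer(n_causal_eqtl),
    tissues = tissues,
    tissue_assignment_probs = tissue_assignment_probs,
    mediation_effect = mediation_effect,
    prop_mediated = prop_mediated,
    gwas_n = gwas_n,
    diagnosis_effect = diagnosis_effect,
    tissue_noise_sd = tissue_noise_sd,
    covariate_effects = covariate_effects,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals <= 0 || cfg$n_variants_per_locus <= 0 || cfg$n_loci <= 0)
    abort("dimensions must be positive", class = "neotwas_config_error")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    abort("maf_range must lie within (0, 0.5]", class = "neotwas_config_error")
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    abort("ld_decay must be in [0, 1)", class = "neotwas_config_error")
  if (cfg$h2_cis < 0 || cfg$h2_cis > 1)
    abort("h2_cis must be in [0, 1]", class = "neotwas_config_error")
  if (cfg$n_causal_eqtl > cfg$n_variants_per_locus)
    abort("n_causal_eqtl must not exceed n_variants_per_locus",
          class = "neotwas_config_error")
  if (length(cfg$tissues) < 1 ||
      length(cfg$tissue_assignment_probs) != length(cfg$tissues) ||
      any(cfg$tissue_assignment_probs < 0 | cfg$tissue_assignment_probs > 1))
    abort("tissue assignment probabilities must be in [0, 1], one per tissue",
          class = "neotwas_config_error")
  if (cfg$h2_cis == 1 && cfg$tissue_noise_sd > 0)
    abort("h2_cis = 1 leaves no room for tissue noise",
          class = "neotwas_config_error")
  invisible(cfg)
}

# locus layout: loci are spread 3 Mb apart across autosomes so cis-windows
# (TSS +/- 500 kb) never overlap and LD pruning windows never span loci.
locus_layout <- function(n_loci) {
  chrom <- ((seq_len(n_loci) - 1L) %% 22L) + 1L
  idx_on_chrom <- ave(seq_len(n_loci), chrom, FUN = seq_along)
  start <- (idx_on_chrom - 1L) * 3e6 + 1e6
  tibble(locus = seq_len(n_loci), chrom = paste0("chr", chrom),
         start = start, tss = start + 5e5)
}

#' Simulate LD-structured genotypes
#'
#' Dosages are generated from a stationary AR(1) Gaussian copula: two latent
#' standard-normal haplotypes per individual follow an AR(1) process along
#' each locus and are thresholded at the allele frequency.  Because
#' thresholding attenuates correlation, the latent correlation for each
#' adjacent pair is calibrated (bivariate-normal inversion) so the realized
#' dosage correlation matches `ld_decay`.  Loci are mutually unlinked.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()] with `n_loci * n_variants_per_locus`
#'   variants; the locus index of each variant is in `panel$variants$locus`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_variants_per_locus
  layout <- locus_layout(config$n_loci)
  cache <- new.env(parent = emptyenv())
  blocks <- vector("list", config$n_loci)
  vmeta <- vector("list", config$n_loci)
  alleles <- c("A", "C", "G", "T")
  for (l in seq_len(config$n_loci)) {
    # MAFs drift slowly along the locus (LD partners share frequency in
    # real panels); a reflected random walk keeps them inside maf_range
    # while letting the calibrated copula reach the target correlation.
    f <- numeric(m)
    f[1] <- runif(1, config$maf_range[1], config$maf_range[2])
    if (m > 1) {
      step <- 0.08 * diff(config$maf_range)
      for (j in 2:m) {
        cand <- f[j - 1] + rnorm(1, sd = step)
        lo <- config$maf_range[1]; hi <- config$maf_range[2]
        while (cand < lo || cand > hi) {
          if (cand < lo) cand <- 2 * lo - cand
          if (cand > hi) cand <- 2 * hi - cand
        }
        f[j] <- cand
      }
    }
    q <- qnorm(f)
    # per-step latent correlations, memoized on a rounded frequency grid
    rho <- numeric(max(m - 1, 0))
    if (m > 1 && config$ld_decay > 0) {
      for (j in seq_len(m - 1)) {
        key <- sprintf("%.3f_%.3f", round(min(f[j], f[j + 1]), 3),
                       round(max(f[j], f[j + 1]), 3))
        if (is.null(cache[[key]])) {
          cache[[key]] <- calibrate_latent_rho(config$ld_decay,
                                               round(f[j], 3), round(f[j + 1], 3))
        }
        rho[j] <- cache[[key]]
      }
    }
    hap <- function() {
      x <- matrix(0, n, m)
      x[, 1] <- rnorm(n)
      if (m > 1) for (j in 2:m) {
        x[, j] <- rho[j - 1] * x[, j - 1] + sqrt(1 - rho[j - 1]^2) * rnorm(n)
      }
      x
    }
    dos <- (hap() < rep(q, each = n)) + (hap() < rep(q, each = n))
    storage.mode(dos) <- "double"
    blocks[[l]] <- dos
    a1 <- sample(alleles, m, replace = TRUE)
    a2 <- map_chr_other(a1)
    vmeta[[l]] <- tibble(
      id = sprintf("rs%d_%d", l, seq_len(m)),
      chrom = layout$chrom[l],
      pos = as.integer(layout$start[l] + round(seq(0, 999000, length.out = m))),
      allele_effect = a1, allele_other = a2, locus = l
    )
  }
  dosages <- do.call(cbind, blocks)
  rownames(dosages) <- sprintf("ind%04d", seq_len(n))
  panel <- genotype_panel(dosages, bind_rows(vmeta))
  attr(panel, "layout") <- layout
  panel
}

# transition partner allele: A/G and C/T pairs are never strand-ambiguous,
# so harmonization keeps every simulated variant
map_chr_other <- function(a1) {
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  unname(partner[a1])
}

#' Simulate multi-tissue expression with a shared cis-genetic component
#'
#' For gene g with causal standardized dosages `Z_c` and effects `b`,
#' expression in tissue t of individual i is
#' `y = Z_c b + diagnosis_effect * dx + delta_t + eps_it` where the genetic
#' component `Z_c b` is shared across all tissues of the individual, `dx` is
#' a Bernoulli(0.5) case indicator, `delta_t` an optional tissue-level noise
#' term and `eps` i.i.d. residual noise.  Effects are scaled so the genetic
#' component explains exactly `h2_cis` of unit total variance (realized h2
#' recorded in the ground truth).
#'
#' @param panel output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return List with `expression` (list of [expression_set()] per tissue),
#'   `annotation` (tibble gene/chrom/tss), and `truth` (tibble per gene:
#'   causal indices, effect vectors, realized h2, mediated flag).
#' @export
simulate_expression <- function(panel, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  if (n < 2) abort("need at least 2 individuals")
  layout <- attr(panel, "layout") %||% locus_layout(config$n_loci)
  genes <- sprintf("gene%04d", seq_len(config$n_loci))
  inds <- panel$sample_ids
  diagnosis <- rbinom(n, 1, 0.5)
  age <- round(runif(n, 65, 95), 1)
  sex <- rbinom(n, 1, 0.5)
  pmi <- round(runif(n, 2, 24), 1)
  batch <- rbinom(n, 1, 0.5)
  cov_eff <- config$covariate_effects %||% c(age = 0, sex = 0, pmi = 0, batch = 0)

  # tissue membership: Bernoulli per tissue, everyone in >= 1 tissue
  member <- sapply(config$tissue_assignment_probs,
                   function(p) rbinom(n, 1, p) == 1)
  if (is.null(dim(member))) member <- matrix(member, nrow = n)
  none <- rowSums(member) == 0
  member[none, which.max(config$tissue_assignment_probs)] <- TRUE

  h2 <- config$h2_cis
  m <- config$n_variants_per_locus
  genetic <- matrix(0, n, config$n_loci)
  truth <- vector("list", config$n_loci)
  n_med <- round(config$prop_mediated * config$n_loci)
  mediated <- seq_len(config$n_loci) %in% sample.int(config$n_loci, n_med)
  for (l in seq_len(config$n_loci)) {
    cols <- which(panel$variants$locus == l)
    causal_local <- sort(sample.int(m, config$n_causal_eqtl))
    beta <- rep(0, m)
    if (h2 > 0) {
      Z <- standardize_columns(panel$dosages[, cols[causal_local], drop = FALSE])
      b0 <- rnorm(config$n_causal_eqtl)
      g <- drop(Z %*% b0)
      vg <- var(g)
      scale <- if (vg > 0) sqrt(h2 / vg) else 0
      g <- g * scale
      beta[causal_local] <- b0 * scale
      genetic[, l] <- g
    }
    realized <- if (h2 > 0) var(genetic[, l]) else 0
    is_med <- mediated[l]
    truth[[l]] <- tibble(
      gene = genes[l], locus = l,
      causal_local = list(causal_local),
      beta_std = list(beta),
      true_h2 = h2, realized_h2 = realized,
      mediated = is_med,
      gamma = if (is_med) config$mediation_effect else 0
    )
  }

  covariate_signal <- cov_eff["age"] * as.numeric(scale(age)) +
    cov_eff["sex"] * sex + cov_eff["pmi"] * as.numeric(scale(pmi)) +
    cov_eff["batch"] * batch

  es <- list()
  for (t in seq_along(config$tissues)) {
    idx <- which(member[, t])
    ns <- length(idx)
    if (ns == 0) next
    delta <- if (config$tissue_noise_sd > 0)
      matrix(rnorm(config$n_loci * ns, sd = config$tissue_noise_sd),
             config$n_loci, ns) else 0
    eps <- matrix(rnorm(config$n_loci * ns, sd = sqrt(max(1 - h2, 0))),
                  config$n_loci, ns)
    vals <- t(genetic[idx, , drop = FALSE]) + delta + eps +
      rep(config$diagnosis_effect * diagnosis[idx] + covariate_signal[idx],
          each = config$n_loci)
    rownames(vals) <- genes
    sample_ids <- paste0(inds[idx], "_", config$tissues[t])
    colnames(vals) <- sample_ids
    covs <- tibble(
      sample_id = sample_ids, individual_id = inds[idx],
      diagnosis = diagnosis[idx], age = age[idx], sex = sex[idx],
      pmi = pmi[idx], batch = batch[idx]
    )
    es[[config$tissues[t]]] <- expression_set(
      vals, covs, setNames(inds[idx], sample_ids), tissue = config$tissues[t])
  }

  annotation <- tibble(gene = genes, chrom = layout$chrom, tss = layout$tss)
  list(expression = es, annotation = annotation,
       truth = bind_rows(truth))
}

#' Simulate GWAS summary statistics with expression-mediated signal
#'
#' Z-scores are drawn analytically at the locus level:
#' `z = sqrt(N) * Lambda alpha + MVN(0, Lambda)` where `Lambda` is the
#' empirical dosage correlation (LD) matrix of the locus and
#' `alpha = gamma * beta` the SNP-level mediated effect on the standardized
#' scale (`gamma` the per-gene mediation effect, `beta` the eQTL effect
#' vector).  `beta_hat = z / sqrt(N)` and `se = 1 / sqrt(N)`.
#'
#' @param panel output of [simulate_genotypes()].
#' @param truth `truth` tibble from [simulate_expression()].
#' @param config the same [sim_config()].
#' @return A tibble GWAS summary: `id, chrom, pos, allele_effect,
#'   allele_other, beta, se, z, n`.
#' @export
simulate_gwas_summary <- function(panel, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  N <- config$gwas_n
  out <- vector("list", nrow(truth))
  for (k in seq_len(nrow(truth))) {
    l <- truth$locus[k]
    cols <- which(panel$variants$locus == l)
    Z <- standardize_columns(panel$dosages[, cols, drop = FALSE])
    Lambda <- crossprod(Z) / (nrow(Z) - 1)
    alpha <- truth$gamma[k] * truth$beta_std[[k]]
    mu <- sqrt(N) * drop(Lambda %*% alpha)
    z <- mu + drop(rmvnorm_chol(1, Lambda))
    v <- panel$variants[cols, ]
    out[[k]] <- tibble(
      id = v$id, chrom = v$chrom, pos = v$pos,
      allele_effect = v$allele_effect, allele_other = v$allele_other,
      beta = z / sqrt(N), se = 1 / sqrt(N), z = z, n = N
    )
  }
  bind_rows(out)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_expression()] and [simulate_gwas_summary()] under one config.
#'
#' @param config a [sim_config()].
#' @return List with `panel`, `expression`, `annotation`, `truth`, `gwas`,
#'   and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  panel <- simulate_genotypes(config)
  expr <- simulate_expression(panel, config)
  gwas <- simulate_gwas_summary(panel, expr$truth, config)
  list(panel = panel, expression = expr$expression,
       annotation = expr$annotation, truth = expr$truth,
       gwas = gwas, config = config)
}
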