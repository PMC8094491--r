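# Post-association refinement: joint/conditional testing among overlapping
# significant genes, SMR replication, and Bayesian colocalization.

#' Group significant genes into loci
#'
#' Connected components of genes whose cis-windows overlap on a
#' chromosome: the unit at which joint/conditional testing operates.
#'
#' @param genes tibble `gene, chrom, tss` for the significant genes.
#' @param flank cis-window half-width (default 5e5).
#' @return The tibble with an added integer `locus` column.
#' @export
define_loci <- function(genes, flank = 5e5) {
  genes <- arrange(genes, .data$chrom, .data$tss)
  locus <- integer(nrow(genes))
  cur <- 0L
  last_chrom <- ""
  last_end <- -Inf
  for (i in seq_len(nrow(genes))) {
    start <- genes$tss[i] - flank
    new_locus <- genes$chrom[i] != last_chrom || start > last_end
    if (new_locus) {
      cur <- cur + 1L
      last_end <- genes$tss[i] + flank
    } else {
      last_end <- max(last_end, genes$tss[i] + flank)
    }
    locus[i] <- cur
    last_chrom <- genes$chrom[i]
  }
  mutate(genes, locus = locus)
}

#' Correlation of predicted expression between genes
#'
#' `Omega_ij = w_i' V w_j / sqrt(w_i' V w_i  w_j' V w_j)` over the union of
#' the genes' weighted variants, with `V` the shrunk LD matrix of that
#' union in the reference panel.  Weights are zero-padded to the union.
#'
#' @param weight_list list of `weight_model` for genes sharing a
#'   chromosome.
#' @param ld_panel LD reference [genotype_panel()].
#' @param shrink identity shrinkage for V (default 0.05).
#' @return Gene-by-gene correlation matrix with unit diagonal.
#' @export
predicted_expression_correlation <- function(weight_list, ld_panel,
                                             shrink = 0.05) {
  union_ids <- unique(unlist(lapply(weight_list, \(w) w$variant_ids)))
  idx <- match(union_ids, ld_panel$variants$id)
  if (anyNA(idx)) abort("weighted variants missing from the LD panel")
  Z <- standardize_columns(impute_mean(ld_panel$dosages[, idx, drop = FALSE]))
  V <- ld_shrink(cor(Z), shrink)
  W <- vapply(weight_list, function(w) {
    out <- numeric(length(union_ids))
    out[match(w$variant_ids, union_ids)] <- w$weights
    out
  }, numeric(length(union_ids)))
  S <- t(W) %*% V %*% W
  d <- sqrt(diag(S))
  omega <- S / tcrossprod(d)
  diag(omega) <- 1
  dimnames(omega) <- list(names(weight_list), names(weight_list))
  omega
}

# conditional z of each element of z_i given the selected set S
conditional_z <- function(z, omega, i, S) {
  if (length(S) == 0) return(z[i])
  Oss_inv <- solve(omega[S, S, drop = FALSE])
  ois <- omega[i, S, drop = FALSE]
  denom <- 1 - drop(ois %*% Oss_inv %*% t(ois))
  if (denom <= 1e-8) return(NA_real_)  # collinear with the selected set
  (z[i] - drop(ois %*% Oss_inv %*% z[S])) / sqrt(denom)
}

#' Joint/conditional probability (JCP) testing within a locus
#'
#' Forward selection on the multivariate-normal model of TWAS z-scores:
#' repeatedly add the gene with the largest conditional |Z| given the
#' selected set, as long as some remaining gene stays significant after BH
#' over the remaining conditional tests.  Selected genes are classified
#' `joint` (reported with their joint Z from the selected-set model);
#' the rest are `marginal` with their conditional Z.  A BH correction over
#' the joint p-values can still demote a selected gene to `dropped`.
#' Genes collinear with the selected set get `marginal` with a flag.
#' Greedy ties break by gene id, so the result is input-order invariant.
#'
#' @param z_marginal named vector of marginal TWAS z-scores (all initially
#'   significant genes of the locus).
#' @param omega predicted-expression correlation matrix from
#'   [predicted_expression_correlation()] (matching names).
#' @param significance_q BH threshold for both the stopping rule and the
#'   joint-gene demotion (default 0.05).
#' @return Tibble: `gene, z_marginal, z_joint, z_conditional, jcp_p,
#'   class` with `class` in `{joint, marginal, dropped}`.
#' @export
jcp <- function(z_marginal, omega, significance_q = 0.05) {
  genes <- sort(names(z_marginal))
  z <- z_marginal[genes]
  omega <- omega[genes, genes, drop = FALSE]
  if (length(genes) == 1) {
    p1 <- 2 * pnorm(-abs(z))
    return(tibble(gene = genes, z_marginal = unname(z), z_joint = unname(z),
                  z_conditional = NA_real_, jcp_p = unname(p1),
                  class = if (p1 < significance_q) "joint" else "dropped"))
  }
  S <- character(0)
  repeat {
    rest <- setdiff(genes, S)
    if (length(rest) == 0) break
    zc <- vapply(rest, function(g) conditional_z(z, omega, g, S), numeric(1))
    pc <- 2 * pnorm(-abs(zc))
    pc[is.na(zc)] <- 1
    qc <- bh_fdr(pc)
    if (!any(qc < significance_q, na.rm = TRUE)) break
    cand <- rest[which(qc < significance_q)]
    pick <- cand[order(-abs(zc[match(cand, rest)]), cand)][1]
    S <- c(S, pick)
  }
  res <- tibble(gene = genes, z_marginal = unname(z),
                z_joint = NA_real_, z_conditional = NA_real_,
                jcp_p = NA_real_, class = "marginal")
  if (length(S) > 0) {
    Oss_inv <- solve(omega[S, S, drop = FALSE])
    zj <- drop(Oss_inv %*% z[S]) / sqrt(diag(Oss_inv))
    sel <- match(S, res$gene)
    res$z_joint[sel] <- zj
    res$jcp_p[sel] <- 2 * pnorm(-abs(zj))
    res$class[sel] <- "joint"
    qj <- bh_fdr(res$jcp_p[sel])
    res$class[sel][qj >= significance_q] <- "dropped"
  }
  marg <- which(res$class == "marginal")
  for (i in marg) {
    zc <- conditional_z(z, omega, res$gene[i], S)
    res$z_conditional[i] <- zc
    res$jcp_p[i] <- if (is.na(zc)) 1 else 2 * pnorm(-abs(zc))
  }
  res
}

#' Condition GWAS SNP z-scores on selected genes
#'
#' For each SNP s, `z_cond = (z_s - rho_sS Omega_SS^-1 Z_S) /
#' sqrt(1 - rho_sS Omega_SS^-1 rho_Ss)` with
#' `rho_si = (V w_i)_s / sqrt(w_i' V w_i)` the correlation between the SNP
#' and gene i's predicted expression.  SNPs collinear with the predictors
#' return NA.
#'
#' @param z_snp named vector of locus SNP z-scores (names = variant ids,
#'   present in the panel).
#' @param weight_list list of `weight_model` for the SELECTED genes.
#' @param z_genes marginal TWAS z of the selected genes (same order).
#' @param ld_panel LD reference [genotype_panel()].
#' @param shrink identity shrinkage for V.
#' @return Tibble `id, z, z_conditional`.
#' @export
conditional_snp_z <- function(z_snp, weight_list, z_genes, ld_panel,
                              shrink = 0.05) {
  snp_ids <- names(z_snp)
  union_ids <- unique(c(snp_ids, unlist(lapply(weight_list, \(w) w$variant_ids))))
  idx <- match(union_ids, ld_panel$variants$id)
  if (anyNA(idx)) abort("variants missing from the LD panel")
  Z <- standardize_columns(impute_mean(ld_panel$dosages[, idx, drop = FALSE]))
  V <- ld_shrink(cor(Z), shrink)
  dimnames(V) <- list(union_ids, union_ids)
  W <- vapply(weight_list, function(w) {
    out <- numeric(length(union_ids))
    out[match(w$variant_ids, union_ids)] <- w$weights
    out
  }, numeric(length(union_ids)))
  denom <- sqrt(diag(t(W) %*% V %*% W))
  rho <- (V %*% W) / rep(denom, each = length(union_ids))  # SNP x gene
  omega_ss <- crossprod(W, V %*% W) / tcrossprod(denom)
  Oss_inv <- solve(omega_ss)
  rs <- rho[snp_ids, , drop = FALSE]
  adj <- drop(rs %*% Oss_inv %*% z_genes)
  v <- 1 - rowSums((rs %*% Oss_inv) * rs)
  num <- z_snp - adj
  # a SNP collinear with the predictors is fully explained when its residual
  # numerator vanishes (self-conditioning); otherwise the quotient is
  # undefined
  zc <- ifelse(v > 1e-8, num / sqrt(pmax(v, 1e-12)),
               ifelse(abs(num) < 1e-6, 0, NA_real_))
  tibble(id = snp_ids, z = unname(z_snp), z_conditional = unname(zc))
}

#' Summary-data Mendelian randomization test
#'
#' `T = z_e^2 z_g^2 / (z_e^2 + z_g^2)`, chi-square with 1 df under the null
#' of no mediation; `z_e` is the top-eQTL z and `z_g` the GWAS z at the
#' same SNP.
#'
#' @param z_eqtl_top top-eQTL z-score(s).
#' @param z_gwas_same_snp GWAS z at the same SNP(s).
#' @param m comparisons for an optional BH correction (a fixed replication
#'   count can be supplied); `NULL` for none.
#' @return Tibble `smr_T, smr_p` (plus `smr_q` when `m` is given).
#' @export
smr <- function(z_eqtl_top, z_gwas_same_snp, m = NULL) {
  stopifnot(all(is.finite(z_eqtl_top)), all(is.finite(z_gwas_same_snp)))
  T_ <- z_eqtl_top^2 * z_gwas_same_snp^2 / (z_eqtl_top^2 + z_gwas_same_snp^2)
  out <- tibble(smr_T = T_, smr_p = pchisq(T_, df = 1, lower.tail = FALSE))
  if (!is.null(m)) out$smr_q <- bh_fdr(out$smr_p, m)
  out
}

#' Bayesian colocalization posterior probabilities
#'
#' Wakefield approximate Bayes factors per SNP and trait
#' (`log ABF = 0.5 log(1 - r) + 0.5 z^2 r`, `r = W/(W + se^2)`) assembled
#' into the five-hypothesis posterior (H0 no association ... H4 shared
#' causal variant) by log-sum-exp over single- and shared-causal
#' configurations.  Default prior variances: `W = 0.2^2` for the
#' case-control GWAS (log-odds scale) and `0.15^2` for expression; default
#' priors p1 = p2 = 1e-4, p12 = 1e-5.
#'
#' @param gwas_beta,gwas_se per-SNP GWAS effect and standard error.
#' @param eqtl_beta,eqtl_se per-SNP eQTL effect and standard error (same
#'   SNP order).
#' @param p1,p2,p12 prior probabilities of a GWAS-only, eQTL-only and
#'   shared causal SNP.
#' @param W_gwas,W_eqtl prior effect variances.
#' @return One-row tibble `pp_h0 .. pp_h4` summing to 1.
#' @export
coloc_abf <- function(gwas_beta, gwas_se, eqtl_beta, eqtl_se,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W_gwas = 0.2^2, W_eqtl = 0.15^2) {
  n <- length(gwas_beta)
  if (n < 2) {
    warn("fewer than 2 shared SNPs; colocalization is degenerate")
    return(tibble(pp_h0 = NA_real_, pp_h1 = NA_real_, pp_h2 = NA_real_,
                  pp_h3 = NA_real_, pp_h4 = NA_real_))
  }
  labf <- function(beta, se, W) {
    r <- W / (W + se^2)
    z2 <- (beta / se)^2
    0.5 * log(1 - r) + 0.5 * z2 * r
  }
  l1 <- labf(gwas_beta, gwas_se, W_gwas)
  l2 <- labf(eqtl_beta, eqtl_se, W_eqtl)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of exp(l1_i + l2_j) = exp(s1 + s2) - exp(s12)
  both <- s1 + s2
  lh3 <- if (both > s12) both + log1p(-exp(s12 - both)) else -Inf
  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + lh3,
          h4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  tibble(pp_h0 = pp[1], pp_h1 = pp[2], pp_h2 = pp[3],
         pp_h3 = pp[4], pp_h4 = pp[5])
}

#' Refine significant TWAS genes locus by locus
#'
#' Builds loci from overlapping cis-windows, runs [jcp()] within each, and
#' annotates every gene with SMR (top-eQTL SNP from the gene's top1 weight)
#' and colocalization posteriors.
#'
#' @param twas a `twas_result` from [twas_associate()].
#' @param weight_list the trained `weight_model` list.
#' @param annotation tibble `gene, chrom, tss`.
#' @param gwas GWAS summary tibble.
#' @param training training set (for top-eQTL z-scores), as from
#'   [build_training_set()]; `values` must contain the genes.
#' @param ld_panel LD reference panel.
#' @param fdr significance threshold on `q` (default 0.05).
#' @param smr_m fixed comparison count for SMR replication (default:
#'   number of significant genes).
#' @param flank cis-window half-width.
#' @return Tibble of class `locus_report`: locus, gene, z-scores, JCP
#'   class, SMR and COLOC columns.
#' @export
refine_loci <- function(twas, weight_list, annotation, gwas, training,
                        ld_panel, fdr = 0.05, smr_m = NULL, flank = 5e5) {
  sig <- filter(as_tibble(twas), .data$q < fdr)
  if (nrow(sig) == 0) return(tibble())
  ann <- left_join(sig, annotation, by = "gene")
  loci <- define_loci(select(ann, "gene", "chrom", "tss"), flank)
  zmap <- setNames(sig$z_twas, sig$gene)
  reports <- map(split(loci$gene, loci$locus), function(gs) {
    om <- predicted_expression_correlation(weight_list[gs], ld_panel)
    jcp(zmap[gs], om)
  })
  rep_tbl <- bind_rows(imap(reports, \(r, l) mutate(r, locus = as.integer(l))))
  # SMR at the top marginal eQTL SNP of each gene
  smr_rows <- map(rep_tbl$gene, function(g) {
    wm <- weight_list[[g]]
    a <- annotation[annotation$gene == g, ]
    win <- cis_window(training$panel, a$chrom, a$tss, flank)
    X <- training$panel$dosages[, win, drop = FALSE]
    keep <- colnames(X) <- training$panel$variants$id[win]
    keep <- wm$variant_ids[wm$variant_ids %in% colnames(X)]
    Z <- standardize_columns(impute_mean(X[, keep, drop = FALSE]))
    y <- training$values[g, ]
    r <- drop(cor(Z, y))
    top <- keep[which.max(abs(r))]
    n_ind <- length(unique(training$panel$individual_ids))
    z_e <- r[which.max(abs(r))] * sqrt(n_ind - 2) /
      sqrt(max(1 - r[which.max(abs(r))]^2, 1e-12))
    z_g <- gwas$z[match(top, gwas$id)]
    if (is.na(z_g)) return(tibble(smr_T = NA_real_, smr_p = NA_real_))
    smr(z_e, z_g)
  })
  coloc_rows <- map(rep_tbl$gene, function(g) {
    a <- annotation[annotation$gene == g, ]
    win_ids <- ld_panel$variants$id[cis_window(ld_panel, a$chrom, a$tss, flank)]
    gsub <- gwas[gwas$id %in% win_ids, ]
    eq <- eqtl_summary(training, g, gsub$id)
    shared <- intersect(gsub$id, eq$id)
    if (length(shared) < 2) return(coloc_abf(numeric(0), numeric(0),
                                             numeric(0), numeric(0)))
    gi <- match(shared, gsub$id)
    ei <- match(shared, eq$id)
    coloc_abf(gsub$beta[gi], gsub$se[gi], eq$beta[ei], eq$se[ei])
  })
  out <- bind_cols(rep_tbl, bind_rows(smr_rows), bind_rows(coloc_rows))
  if (!is.null(smr_m) || nrow(out) > 0)
    out$smr_q <- bh_fdr(out$smr_p, smr_m %||% nrow(out))
  class(out) <- c("locus_report", class(out))
  out
}

# marginal eQTL summary statistics of gene g in the training set
eqtl_summary <- function(training, g, ids) {
  idx <- match(ids, training$panel$variants$id)
  ok <- !is.na(idx)
  Z <- standardize_columns(
    impute_mean(training$panel$dosages[, idx[ok], drop = FALSE]))
  y <- training$values[g, ]
  n <- length(y)
  r <- drop(cor(Z, y))
  r[is.na(r)] <- 0
  beta <- r * sd(y)
  se <- sqrt(pmax(1 - r^2, 1e-12) / (n - 2)) * sd(y)
  tibble(id = ids[ok], beta = beta, se = se, z = beta / se)
}
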