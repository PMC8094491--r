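# Shared fixtures, built once per test run.

# a small random panel without LD structure (for algebraic checks)
toy_panel <- function(n = 60, m = 12, seed = 42, chrom = "chr1",
                      pos = NULL, maf = 0.3) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, maf), n, m)
  rownames(dos) <- sprintf("s%03d", seq_len(n))
  variants <- tibble::tibble(
    id = sprintf("v%03d", seq_len(m)), chrom = chrom,
    pos = pos %||% seq(1000, by = 1000, length.out = m),
    allele_effect = "A", allele_other = "G"
  )
  genotype_panel(dos, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoized medium cohort shared across test files
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 400, n_loci = 15,
                        n_variants_per_locus = 16, h2_cis = 0.4,
                        prop_mediated = 0.2, mediation_effect = 0.15,
                        seed = 2024L)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

shared_training <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- shared_cohort()
      prepared <- suppressWarnings(lapply(co$expression, prepare_expression))
      cache <<- build_training_set(prepared, co$panel)
    }
    cache
  }
})

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(q)))
  out <- numeric(length(p))
  out[o] <- pmin(q, 1)
  out
}

# brute-force tie-corrected Kendall tau-b over all pairs
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
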