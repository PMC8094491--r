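# End-to-end orchestration with per-stage outputs and manifests.

#' Pipeline configuration
#'
#' @param input_dir directory holding `genotypes.{bed,bim,fam}`,
#'   `expression_<tissue>.tsv`, `covariates_<tissue>.tsv`,
#'   `annotation.tsv`, `gwas.tsv` and optionally `markers.tsv`,
#'   `edges.tsv` (the layout written by [write_cohort()]).
#' @param out_dir run directory for stage outputs.
#' @param tissues tissue labels to load.
#' @param maf_min,miss_max,maf_max variant QC thresholds.
#' @param h2_p heritability gate p-value threshold (default 0.01).
#' @param fdr significance threshold (default 0.05).
#' @param flank cis-window half-width (default 5e5).
#' @param k_folds cross-validation folds (default 5).
#' @param models weight models to fit.
#' @param B_bootstrap bootstraps for gene-set expansion.
#' @param sd_multiplier SD cutoff for expansion (default 1.3).
#' @param stages character vector of stages to run, a subset (in order) of
#'   `qc, normalize, h2, train, assoc, refine, expand`.
#' @param seed integer seed for every stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, tissues,
                            maf_min = 0.01, miss_max = 0.1, maf_max = 0.40,
                            h2_p = 0.01, fdr = 0.05, flank = 5e5,
                            k_folds = 5,
                            models = c("top1", "blup", "lasso", "enet"),
                            B_bootstrap = 50, sd_multiplier = 1.3,
                            stages = c("qc", "normalize", "h2", "train",
                                       "assoc", "refine", "expand"),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!dir.exists(input_dir)) abort("input_dir does not exist")
  stopifnot(h2_p > 0, h2_p < 1, fdr > 0, fdr < 1, flank > 0, k_folds >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_manifest <- function(dir, stage, params, inputs, rows) {
  manifest <- list(
    stage = stage, params = params,
    inputs = lapply(inputs, \(f) unname(tools::md5sum(f))),
    rows = rows
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_stage_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Stages execute in fixed order (qc, normalize, h2, train, assoc, refine,
#' expand); each writes its outputs plus a manifest (input hashes,
#' parameters, row counts) into `out_dir`.  Any stage error aborts with
#' the stage name in the condition message.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return `out_dir`, invisibly; stage outputs live there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  state <- new.env(parent = emptyenv())

  run_stage("qc", function() {
    panel <- read_plink(file.path(cfg$input_dir, "genotypes"))
    filtered <- filter_variants(panel, cfg$maf_min, cfg$miss_max, cfg$maf_max)
    state$panel <- filtered
    out <- write_stage_tsv(filtered$variants, file.path(cfg$out_dir, "qc_variants.tsv"))
    stage_manifest(cfg$out_dir, "qc",
                   cfg[c("maf_min", "miss_max", "maf_max")],
                   list(bed = file.path(cfg$input_dir, "genotypes.bed")),
                   nrow(filtered$variants))
  })
  if (is.null(state$panel))
    state$panel <- read_plink(file.path(cfg$input_dir, "genotypes"))

  run_stage("normalize", function() {
    prepared <- list()
    for (tissue in cfg$tissues) {
      vals <- read_tsv_matrix(file.path(cfg$input_dir,
                                        paste0("expression_", tissue, ".tsv")))
      covs <- read.table(file.path(cfg$input_dir,
                                   paste0("covariates_", tissue, ".tsv")),
                         header = TRUE, sep = "\t")
      es <- expression_set(vals, covs,
                           setNames(covs$individual_id, covs$sample_id),
                           tissue = tissue)
      prepared[[tissue]] <- prepare_expression(es)
      write_tsv_matrix(prepared[[tissue]]$values,
                       file.path(cfg$out_dir, paste0("normalized_", tissue, ".tsv")))
    }
    state$expression <- prepared
    stage_manifest(cfg$out_dir, "normalize", list(scale = 1),
                   list(), sum(vapply(prepared, \(e) nrow(e$values), integer(1))))
  })

  state$annotation <- read_annotation(file.path(cfg$input_dir, "annotation.tsv"))

  run_stage("h2", function() {
    training <- build_training_set(state$expression, state$panel)
    state$training <- training
    est <- estimate_cis_h2(training$panel, training$values, state$annotation,
                           flank = cfg$flank)
    state$h2 <- est
    write_stage_tsv(est, file.path(cfg$out_dir, "h2_estimates.tsv"))
    stage_manifest(cfg$out_dir, "h2", list(flank = cfg$flank, h2_p = cfg$h2_p),
                   list(), nrow(est))
  })

  run_stage("train", function() {
    wl <- train_weights(state$training, state$annotation, state$h2,
                        k = cfg$k_folds, flank = cfg$flank,
                        models = cfg$models, seed = cfg$seed)
    state$weights <- wl
    idx <- bind_rows(lapply(wl, \(w) tibble(
      gene = w$gene, model = w$model_name, cv_r2 = w$cv_r2, cv_p = w$cv_p,
      h2 = w$h2, n_snps = length(w$variant_ids))))
    write_stage_tsv(idx, file.path(cfg$out_dir, "weights_index.tsv"))
    per_gene <- bind_rows(lapply(wl, \(w) mutate(w$alleles, gene = w$gene,
                                                 weight = w$weights)))
    write_stage_tsv(per_gene, file.path(cfg$out_dir, "weights.tsv"))
    stage_manifest(cfg$out_dir, "train",
                   cfg[c("k_folds", "models", "seed")], list(), length(wl))
  })

  state$gwas <- read_gwas(file.path(cfg$input_dir, "gwas.tsv"))

  run_stage("assoc", function() {
    res <- twas_associate(state$weights, state$gwas, state$panel)
    state$twas <- res
    write_stage_tsv(res, file.path(cfg$out_dir, "twas.tsv"))
    stage_manifest(cfg$out_dir, "assoc", list(fdr = cfg$fdr), list(), nrow(res))
  })

  run_stage("refine", function() {
    rep <- refine_loci(state$twas, state$weights, state$annotation,
                       state$gwas, state$training, state$panel,
                       fdr = cfg$fdr, flank = cfg$flank)
    state$refined <- rep
    write_stage_tsv(rep, file.path(cfg$out_dir, "locus_report.tsv"))
    stage_manifest(cfg$out_dir, "refine", list(fdr = cfg$fdr), list(),
                   nrow(rep))
  })

  run_stage("expand", function() {
    edges_path <- file.path(cfg$input_dir, "edges.tsv")
    if (!file.exists(edges_path)) return(invisible(NULL))
    edges <- read.table(edges_path, header = TRUE, sep = "\t")
    hits <- if (!is.null(state$refined) && nrow(state$refined) > 0)
      state$refined$gene else character(0)
    rows <- map(hits, function(g) {
      ex <- expand_gene_set(g, state$expression, state$annotation, edges,
                            B = cfg$B_bootstrap, s = cfg$sd_multiplier,
                            seed = cfg$seed)
      tibble(gene = g, n_included = length(ex$included_genes),
             broad = length(ex$broad_set), narrow = length(ex$narrow_set))
    })
    out <- bind_rows(rows)
    write_stage_tsv(out, file.path(cfg$out_dir, "expansion.tsv"))
    stage_manifest(cfg$out_dir, "expand",
                   cfg[c("B_bootstrap", "sd_multiplier")], list(), nrow(out))
  })

  invisible(cfg$out_dir)
}

#' Summaries and plot data for a finished run
#'
#' @param run_dir the pipeline output directory (needs `twas.tsv`).
#' @return List: `genes` (association table sorted by q), `qq` (expected
#'   vs observed -log10 p plus the genomic-inflation-style lambda), and
#'   `loci` (locus classification table if present).
#' @export
report_run <- function(run_dir) {
  twas_path <- file.path(run_dir, "twas.tsv")
  if (!file.exists(twas_path)) abort("association outputs not found")
  tw <- as_tibble(read.table(twas_path, header = TRUE, sep = "\t"))
  genes <- arrange(tw, .data$q)
  qq <- if (nrow(tw) > 0) {
    obs <- sort(tw$p)
    n <- length(obs)
    lambda <- median(tw$z_twas^2) / qchisq(0.5, 1)
    tibble(expected = -log10((seq_len(n) - 0.5) / n),
           observed = -log10(obs)) |>
      structure(lambda = lambda)
  } else tibble(expected = numeric(0), observed = numeric(0))
  loci_path <- file.path(run_dir, "locus_report.tsv")
  loci <- if (file.exists(loci_path) && file.size(loci_path) > 1)
    tryCatch(as_tibble(read.table(loci_path, header = TRUE, sep = "\t")),
             error = function(e) tibble()) else tibble()
  list(genes = genes, qq = qq, loci = loci)
}
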