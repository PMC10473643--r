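# Staged pipeline orchestration: simulate -> preprocess -> train ->
# associate -> compare, each stage persisting tab-separated outputs plus a
# machine-readable JSON run log, deterministically under one seed.

#' Build a run configuration
#'
#' Merges user settings over the defaults. Thresholds default to the
#' published values: MAF filter 0.05, outlier alpha 0.001, FDR 0.05,
#' cis flank 1 Mb, external-model predictive-p filter 0.05.
#'
#' @param config_file Optional YAML file with a nested list of settings.
#' @param ... Named overrides applied after the file (e.g. `seed = 3`,
#'   `sim = list(n_genes = 20)`).
#' @return A `run_config` list: `seed`, `out_dir`, `sim` (arguments to
#'   [sim_config()]), and `thresholds` (maf, outlier_alpha, fdr, flank,
#'   model_filter_p, alpha, nfolds, k_pc, k_sv).
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = "metawas_run",
    sim = list(),
    thresholds = list(maf = 0.05, outlier_alpha = 0.001, fdr = 0.05,
                      flank = 1e6, model_filter_p = 0.05,
                      alpha = 0.5, nfolds = 10, k_pc = 10, k_sv = 10)
  )
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file)
    cfg <- modifyList(cfg, yaml::read_yaml(config_file))
  }
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_upstream <- function(cfg, files, stage) {
  paths <- stage_path(cfg, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' needs missing upstream output(s): ",
         paste(missing, collapse = ", "),
         " (run the earlier stages first)")
  invisible(paths)
}

write_run_log <- function(cfg, stage, params, counts, inputs = character()) {
  log <- list(
    stage = stage, seed = cfg$seed, params = params, counts = counts,
    input_hashes = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(log, stage_path(cfg, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(log)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (writes the VCF, annotation, omic, covariate, trait,
#' GWAS, and truth tables), `preprocess` (residual matrices + retained
#' samples), `train` (model database per layer), `associate` (association
#' table + per-trait report), `compare` (concordance tables). Each stage is
#' deterministic given the seed, reads only persisted upstream outputs, and
#' writes a JSON run log with parameters, counts, and input hashes.
#'
#' @param name Stage name.
#' @param cfg A [run_config()].
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(name = c("simulate", "preprocess", "train",
                               "associate", "compare"),
                      cfg = run_config()) {
  name <- match.arg(name)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(cfg),
         preprocess = stage_preprocess(cfg),
         train = stage_train(cfg),
         associate = stage_associate(cfg),
         compare = stage_compare(cfg))
}

#' Run the full pipeline
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the compare-stage result.
#' @export
run_pipeline <- function(cfg = run_config()) {
  for (s in c("simulate", "preprocess", "train", "associate", "compare"))
    res <- run_stage(s, cfg)
  invisible(res)
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
  cohort <- simulate_cohort(sc, keep_gwas_dosages = FALSE)
  write_vcf_dosage(cohort$geno$variants, cohort$geno$dosages,
                   stage_path(cfg, "genotypes.vcf"))
  write_tsv_table(cohort$geno$variants, stage_path(cfg, "variants.tsv"))
  write_tsv_table(cohort$geno$annotation, stage_path(cfg, "annotation.tsv"))
  cov <- data.frame(sample_id = rownames(cohort$covariates),
                    cohort$covariates)
  write_tsv_table(cov, stage_path(cfg, "covariates.tsv"))
  for (lay in names(cohort$omics)) {
    write_omics(cohort$omics[[lay]],
                stage_path(cfg, paste0("omics_", safe_layer(lay), ".tsv")))
    write_tsv_table(cohort$omics[[lay]]$feature_map,
                    stage_path(cfg, paste0("features_", safe_layer(lay),
                                           ".tsv")))
  }
  write_tsv_table(cohort$trait, stage_path(cfg, "trait.tsv"))
  write_tsv_table(cohort$gwas, stage_path(cfg, "gwas_trait.tsv"))
  truth_tab <- do.call(rbind, lapply(names(cohort$truth$causal), function(g)
    data.frame(gene_id = g, variant_id = cohort$truth$causal[[g]],
               effect = unname(cohort$truth$effects$protein[[g]]),
               alpha = unname(cohort$truth$alpha[g]),
               stringsAsFactors = FALSE)))
  write_tsv_table(truth_tab, stage_path(cfg, "truth.tsv"))
  writeLines(names(cohort$omics), stage_path(cfg, "layers.txt"))
  write_run_log(cfg, "simulate",
                params = unclass(sc),
                counts = list(n_variants = nrow(cohort$geno$variants),
                              n_samples = nrow(cohort$geno$dosages),
                              n_layers = length(cohort$omics)))
  invisible(cohort)
}

safe_layer <- function(lay) gsub("[^A-Za-z0-9]", "_", lay)

read_layers <- function(cfg) readLines(stage_path(cfg, "layers.txt"))

stage_preprocess <- function(cfg) {
  require_upstream(cfg, c("covariates.tsv", "layers.txt"), "preprocess")
  covd <- read_tsv_table(stage_path(cfg, "covariates.tsv"))
  covariates <- covd[, -1, drop = FALSE]
  rownames(covariates) <- covd$sample_id
  th <- cfg$thresholds
  out <- list()
  for (lay in read_layers(cfg)) {
    f <- paste0("omics_", safe_layer(lay), ".tsv")
    require_upstream(cfg, f, "preprocess")
    fmap <- read_tsv_table(stage_path(cfg, paste0("features_",
                                                  safe_layer(lay), ".tsv")))
    om <- load_omics(stage_path(cfg, f), fmap, layer = lay)
    pp <- preprocess_omics(om, covariates, k_pc = th$k_pc, k_sv = th$k_sv,
                           alpha = th$outlier_alpha)
    write_omics(pp$residuals,
                stage_path(cfg, paste0("residuals_", safe_layer(lay),
                                       ".tsv")))
    writeLines(pp$retained,
               stage_path(cfg, paste0("retained_", safe_layer(lay), ".txt")))
    out[[lay]] <- pp
    write_run_log(cfg, paste0("preprocess_", safe_layer(lay)),
                  params = list(k_pc = th$k_pc, k_sv = th$k_sv,
                                alpha = th$outlier_alpha),
                  counts = pp$log,
                  inputs = stage_path(cfg, f))
  }
  invisible(out)
}

stage_train <- function(cfg) {
  require_upstream(cfg, c("genotypes.vcf", "annotation.tsv",
                          "gwas_trait.tsv", "layers.txt"), "train")
  th <- cfg$thresholds
  geno <- load_dosages(stage_path(cfg, "genotypes.vcf"),
                       maf_threshold = th$maf)
  annotation <- read_tsv_table(stage_path(cfg, "annotation.tsv"))
  gwas <- read_tsv_table(stage_path(cfg, "gwas_trait.tsv"))
  harm <- harmonize_gwas(geno$variants, gwas)
  gwas_ids <- harm$variant_id[harm$present]
  dbs <- list()
  for (lay in read_layers(cfg)) {
    f <- paste0("residuals_", safe_layer(lay), ".tsv")
    require_upstream(cfg, f, "train")
    fmap <- read_tsv_table(stage_path(cfg, paste0("features_",
                                                  safe_layer(lay), ".tsv")))
    res <- load_omics(stage_path(cfg, f), fmap, layer = lay)
    db <- train_models(geno, annotation, res, gwas_variant_ids = gwas_ids,
                       flank = th$flank, alpha = th$alpha,
                       nfolds = th$nfolds, seed = cfg$seed)
    db <- model_significance(db, fdr_level = th$fdr)
    dbs[[lay]] <- db
    write_model_db(db,
                   stage_path(cfg, paste0("model_weights_", safe_layer(lay),
                                          ".tsv")),
                   stage_path(cfg, paste0("model_summary_", safe_layer(lay),
                                          ".tsv")))
    write_run_log(cfg, paste0("train_", safe_layer(lay)),
                  params = db$meta,
                  counts = list(n_models = nrow(db$summary),
                                n_significant = sum(db$summary$significant),
                                n_candidate_variants = length(gwas_ids)),
                  inputs = stage_path(cfg, f))
  }
  invisible(dbs)
}

stage_associate <- function(cfg) {
  require_upstream(cfg, c("genotypes.vcf", "gwas_trait.tsv", "layers.txt"),
                   "associate")
  th <- cfg$thresholds
  layers <- read_layers(cfg)
  wfiles <- paste0("model_weights_", safe_layer(layers), ".tsv")
  sfiles <- paste0("model_summary_", safe_layer(layers), ".tsv")
  require_upstream(cfg, c(wfiles, sfiles), "associate")
  dbs <- lapply(seq_along(layers), function(i)
    read_model_db(stage_path(cfg, wfiles[i]), stage_path(cfg, sfiles[i])))
  db <- new_model_db(do.call(rbind, lapply(dbs, `[[`, "weights")),
                     do.call(rbind, lapply(dbs, `[[`, "summary")))
  reference <- load_dosages(stage_path(cfg, "genotypes.vcf"),
                            maf_threshold = th$maf)
  gwas <- read_tsv_table(stage_path(cfg, "gwas_trait.tsv"))
  res <- association_scan(db, list(trait = gwas), reference,
                          fdr_level = th$fdr)
  write_tsv_table(res, stage_path(cfg, "associations.tsv"))
  prot <- res[res$layer == "protein", , drop = FALSE]
  if (nrow(prot))
    write_tsv_table(format_association_table(prot),
                    stage_path(cfg, "association_report.tsv"))
  write_run_log(cfg, "associate",
                params = list(fdr = th$fdr),
                counts = list(n_results = nrow(res),
                              n_significant = sum(res$significant)),
                inputs = stage_path(cfg, "gwas_trait.tsv"))
  invisible(res)
}

stage_compare <- function(cfg) {
  require_upstream(cfg, "associations.tsv", "compare")
  res <- read_tsv_table(stage_path(cfg, "associations.tsv"))
  if (length(unique(res$layer)) < 2)
    stop("compare stage needs association results for >= 2 layers in ",
         stage_path(cfg, "associations.tsv"))
  layers <- read_layers(cfg)
  wfiles <- stage_path(cfg, paste0("model_weights_", safe_layer(layers),
                                   ".tsv"))
  sfiles <- stage_path(cfg, paste0("model_summary_", safe_layer(layers),
                                   ".tsv"))
  db <- NULL
  if (all(file.exists(c(wfiles, sfiles)))) {
    dbs <- lapply(seq_along(layers), function(i)
      read_model_db(wfiles[i], sfiles[i]))
    db <- new_model_db(do.call(rbind, lapply(dbs, `[[`, "weights")),
                       do.call(rbind, lapply(dbs, `[[`, "summary")))
  }
  rep <- concordance_report(res, db, base_layer = "protein",
                            fdr_level = cfg$thresholds$fdr)
  write_tsv_table(rep$per_layer, stage_path(cfg, "concordance_layers.tsv"))
  if (!is.null(rep$per_gene))
    write_tsv_table(rep$per_gene, stage_path(cfg, "concordance_genes.tsv"))
  m <- signed_logp_matrix(res)
  write_tsv_table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                  stage_path(cfg, "signed_logp_matrix.tsv"))
  write_run_log(cfg, "compare",
                params = list(base_layer = "protein"),
                counts = list(n_layers = nrow(rep$per_layer),
                              n_positive = rep$sign_test$n_positive),
                inputs = stage_path(cfg, "associations.tsv"))
  invisible(rep)
}
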