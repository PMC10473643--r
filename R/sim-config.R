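#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic cohort: cohort sizes,
#' per-gene LD-block geometry, minor-allele-frequency spectrum, cis
#' heritability, known-covariate and hidden-factor variance structure, the
#' trait-mediation architecture, and the number of expression "tissues".
#'
#' Per omic feature the variance budget is: `cis_h2` (cis-genetic) +
#' `covariate_var` (known covariates) + `hidden_var` (shared hidden factors;
#' 0 when `n_hidden_factors == 0`) + residual noise, summing to 1.
#'
#' @param n_train_samples Training-cohort size (genotyped samples with omics).
#' @param n_gwas_samples Size of the independent GWAS cohort from which
#'   marginal summary statistics are computed.
#' @param n_genes Number of genes; each gene owns one independent LD block.
#' @param n_variants_per_gene Variants per LD block, all within the gene's
#'   cis window.
#' @param ld_decay Target correlation between *dosages* of adjacent variants
#'   in a block, in `[0, 1)`. Non-adjacent correlations decay multiplicatively
#'   (first-order autoregressive structure).
#' @param maf_range Length-2 numeric, the (low, high) minor allele frequency
#'   range in `(0, 0.5]`; per-variant MAFs are drawn uniformly from it.
#' @param n_causal_per_gene Number of causal cis variants per gene.
#' @param cis_h2 Proportion of each omic feature's variance explained by its
#'   cis-genetic component, in `[0, 1)`.
#' @param n_hidden_factors Number of hidden factors shared across features
#'   (surrogate-variable targets); 0 disables them.
#' @param covariate_var,hidden_var Variance shares of the known-covariate and
#'   hidden-factor components per feature.
#' @param mediation_effect_sd Standard deviation of the per-gene mediation
#'   coefficient linking the genetic omic component to the trait (non-null
#'   genes only).
#' @param prop_null_genes Proportion of genes whose mediation coefficient is
#'   exactly 0.
#' @param cross_layer_effect_corr Correlation, in `[-1, 1]`, between the
#'   protein-layer and each expression-layer causal effect vector of a gene.
#' @param n_tissues Number of expression layers ("tissues") to simulate in
#'   addition to the protein layer.
#' @param seed Integer seed; the full generated cohort is a deterministic
#'   function of the configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 5, n_train_samples = 50, n_gwas_samples = 100)
#' cfg$cis_h2
#' @export
sim_config <- function(n_train_samples = 900,
                       n_gwas_samples = 20000,
                       n_genes = 100,
                       n_variants_per_gene = 30,
                       ld_decay = 0.5,
                       maf_range = c(0.05, 0.5),
                       n_causal_per_gene = 3,
                       cis_h2 = 0.3,
                       n_hidden_factors = 3,
                       covariate_var = 0.1,
                       hidden_var = 0.15,
                       mediation_effect_sd = 0.1,
                       prop_null_genes = 0.5,
                       cross_layer_effect_corr = 0.5,
                       n_tissues = 1,
                       seed = 1L) {
  cfg <- list(
    n_train_samples = as.integer(n_train_samples),
    n_gwas_samples = as.integer(n_gwas_samples),
    n_genes = as.integer(n_genes),
    n_variants_per_gene = as.integer(n_variants_per_gene),
    ld_decay = as.numeric(ld_decay),
    maf_range = as.numeric(maf_range),
    n_causal_per_gene = as.integer(n_causal_per_gene),
    cis_h2 = as.numeric(cis_h2),
    n_hidden_factors = as.integer(n_hidden_factors),
    covariate_var = as.numeric(covariate_var),
    hidden_var = as.numeric(hidden_var),
    mediation_effect_sd = as.numeric(mediation_effect_sd),
    prop_null_genes = as.numeric(prop_null_genes),
    cross_layer_effect_corr = as.numeric(cross_layer_effect_corr),
    n_tissues = as.integer(n_tissues),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_train_samples", "n_gwas_samples", "n_genes",
              "n_variants_per_gene", "n_causal_per_gene", "n_tissues")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a count >= 1 (got %s)", nm, cfg[[nm]]))
  }
  if (cfg$n_hidden_factors < 0L) stop("'n_hidden_factors' must be >= 0")
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    stop("'ld_decay' must be in [0, 1)")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("'maf_range' must be (low, high) within (0, 0.5]")
  if (cfg$cis_h2 < 0 || cfg$cis_h2 >= 1)
    stop("'cis_h2' must be in [0, 1)")
  if (cfg$n_causal_per_gene > cfg$n_variants_per_gene)
    stop("'n_causal_per_gene' cannot exceed 'n_variants_per_gene'")
  hv <- if (cfg$n_hidden_factors > 0L) cfg$hidden_var else 0
  if (cfg$covariate_var < 0 || hv < 0 ||
      cfg$cis_h2 + cfg$covariate_var + hv >= 1)
    stop("variance shares cis_h2 + covariate_var + hidden_var must sum to < 1")
  if (cfg$prop_null_genes < 0 || cfg$prop_null_genes > 1)
    stop("'prop_null_genes' must be in [0, 1]")
  if (abs(cfg$cross_layer_effect_corr) > 1)
    stop("'cross_layer_effect_corr' must be in [-1, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes x", x$n_variants_per_gene,
      "variants; n_train =", x$n_train_samples,
      "; n_gwas =", x$n_gwas_samples,
      "; cis_h2 =", x$cis_h2,
      "; tissues =", x$n_tissues, "\n")
  invisible(x)
}

# Derived seed streams, kept below 2^31 for any base seed.
sim_seed <- function(cfg, stream) {
  (abs(cfg$seed) + 7919L * stream) %% .Machine$integer.max
}
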