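# Shared small fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small but non-degenerate cohort: 2 layers, mediated + null genes.
tiny_cohort <- function() {
  memo("tiny", {
    cfg <- sim_config(n_train_samples = 250, n_gwas_samples = 1500,
                      n_genes = 8, n_variants_per_gene = 10,
                      cis_h2 = 0.4, n_tissues = 1,
                      mediation_effect_sd = 0.2, prop_null_genes = 0.5,
                      seed = 42)
    co <- simulate_cohort(cfg)
    co$cfg <- cfg
    co
  })
}

# Models trained on the tiny cohort's protein layer.
tiny_db <- function() {
  memo("tiny_db", {
    co <- tiny_cohort()
    pp <- preprocess_omics(co$omics$protein, co$covariates,
                           k_pc = 5, k_sv = 5)
    harm <- harmonize_gwas(co$geno$variants, co$gwas)
    train_models(co$geno, co$geno$annotation, pp$residuals,
                 gwas_variant_ids = harm$variant_id[harm$present],
                 seed = 7)
  })
}

# Hand (independent) BH step-up oracle: q_(i) = min_{j>=i} m p_(j)/j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  pmin(q_sorted, 1)[order(o)]
}
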