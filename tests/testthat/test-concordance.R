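# Cross-layer comparison suite: signed log p matrices, Spearman
# concordance, the exact sign test, allele orientation, and the weighted
# average decomposition with its sign identity.

test_that("signed log p matrix places entries and honors the display filter", {
  res <- data.frame(
    gene_id = c("g1", "g1", "g2"), layer = c("protein", "expr", "protein"),
    trait = "LDL", z = c(2, -1, 0.5), p = c(0.01, 0.3, 0.6),
    q = c(0.04, 0.6, 0.8), signed_log10_p = c(2, -0.52, 0.22),
    direction = c("+", "-", "+"), significant = c(TRUE, FALSE, FALSE))
  m <- signed_logp_matrix(res)
  expect_equal(m["g1", "protein|LDL"], 2)          # z>0, p=0.01 -> +2
  expect_true(is.na(m["g2", "expr|LDL"]))          # absent -> empty cell
  mf <- signed_logp_matrix(res, only_significant = TRUE)
  expect_identical(rownames(mf), "g1")
  # no significant genes -> empty display matrix
  res$significant <- FALSE
  expect_equal(nrow(signed_logp_matrix(res, only_significant = TRUE)), 0L)
  expect_error(signed_logp_matrix(res[res$layer == "protein", ]),
               "2 .layer, trait. contexts")
})

test_that("spearman concordance matches hand-rank computations", {
  a <- c(1, 2, 3, 4)
  expect_equal(spearman_concordance(a, a)$rho, 1)
  expect_equal(spearman_concordance(a, -a)$rho, -1)
  got <- spearman_concordance(a, c(1, 3, 2, 4))
  expect_equal(got$rho, 0.8, tolerance = 1e-12)    # 1 - 6*2/(4*15)
  expect_equal(got$pval,
               cor.test(a, c(1, 3, 2, 4), method = "spearman")$p.value)
  # pairwise-complete deletion
  got2 <- spearman_concordance(c(a, NA), c(1, 3, 2, 4, 9))
  expect_equal(got2$n, 4L)
  expect_error(spearman_concordance(c(1, 2), c(1, 2)), "3 complete")
})

test_that("sign test is the exact upper-tail binomial probability", {
  # 47 positive of 49 reproduces 2.2e-12 to 2 significant figures
  expect_equal(signif(sign_binomial_test(47, 49), 2), 2.2e-12)
  expect_equal(sign_binomial_test(1, 1), 0.5)
  expect_equal(sign_binomial_test(3, 3), 0.125)
  expect_equal(sign_binomial_test(0, 5), 1)
  # monotone decreasing in n_positive at fixed n_total
  p <- vapply(0:20, sign_binomial_test, 0.0, n_total = 20)
  expect_true(all(diff(p) < 0))
  # two-sided option agrees with binom.test
  expect_equal(sign_binomial_test(15, 20, alternative = "two.sided"),
               binom.test(15, 20)$p.value)
})

test_that("orientation to positive GWAS effects is a flagged involution", {
  model <- data.frame(gene_id = "g", variant_id = c("v1", "v2", "v3"),
                      effect_allele = "G", weight = c(0.3, -0.2, 0.1))
  gwas <- data.frame(variant_id = c("v1", "v2", "v3"), z = c(-2, 1, 0))
  v <- orient_to_positive_gwas(model, gwas)
  expect_equal(v$z, c(2, 1, 0))                    # all oriented z >= 0
  expect_equal(v$w, c(-0.3, -0.2, 0.1))            # flip negates the weight
  expect_identical(v$flipped, c(TRUE, FALSE, FALSE))
  expect_identical(v$zero_z, c(FALSE, FALSE, TRUE))
  # all-positive input: identity
  gpos <- data.frame(variant_id = c("v1", "v2", "v3"), z = c(2, 1, 3))
  vp <- orient_to_positive_gwas(model, gpos)
  expect_equal(vp$w, model$weight)
  # applying twice is the identity
  m2 <- data.frame(gene_id = "g", variant_id = v$variant_id,
                   effect_allele = "G", weight = v$w)
  g2 <- data.frame(variant_id = v$variant_id, z = v$z)
  v2 <- orient_to_positive_gwas(m2, g2)
  expect_equal(v2$w, v$w); expect_equal(v2$z, v$z)
})

test_that("weight decomposition matches hand computation and sign identity", {
  one <- data.frame(variant_id = "v1", w = 0.4, z = 2, sigma = 1,
                    flipped = FALSE, zero_z = FALSE)
  expect_equal(weight_decomposition(one), 0.4)
  # the two-variant z-score toy: WA = (2*1 + 1*1) / (2 + 1) = 1 > 0 = sign(z_g)
  toy <- data.frame(variant_id = c("v1", "v2"), w = c(1, 1), z = c(2, 1),
                    sigma = c(1, 1), flipped = FALSE, zero_z = FALSE)
  expect_equal(weight_decomposition(toy), 1)
  # negating all weights negates the average
  toyn <- toy; toyn$w <- -toyn$w
  expect_equal(weight_decomposition(toyn), -1)
  # zero denominator flagged
  z0 <- toy; z0$z <- 0
  expect_warning(wa <- weight_decomposition(z0), "undefined")
  expect_true(is.na(wa))
  # plain-z weighting option
  mix <- data.frame(variant_id = c("a", "b"), w = c(1, 0), z = c(1, 1),
                    sigma = c(1, 3), flipped = FALSE, zero_z = FALSE)
  expect_equal(weight_decomposition(mix, use_sigma = FALSE), 0.5)
  expect_equal(weight_decomposition(mix), 0.25)
})

test_that("decomposition sign equals the gene z-score sign on simulated data", {
  co <- tiny_cohort()
  db <- tiny_db()
  ref <- list(variants = co$geno$variants, dosages = co$gwas_dosages)
  res <- association_scan(db, list(T = co$gwas), ref)
  harm <- harmonize_gwas(co$geno$variants, co$gwas)
  for (i in seq_len(nrow(res))) {
    model <- metawas:::model_entries(db, res$gene_id[i], "protein")
    ld <- ld_covariance(model, ref)
    view <- orient_to_positive_gwas(model, harm,
                                    sigma = setNames(ld$sigma,
                                                     ld$variant_id))
    wa <- weight_decomposition(view)
    if (!is.na(wa) && wa != 0)
      expect_identical(sign(wa), sign(res$z[i]))
  }
})

test_that("overlap and joint-significance classification", {
  mA <- data.frame(gene_id = "g", variant_id = c("v1", "v2"),
                   effect_allele = "G", weight = c(1, 0.5))
  mB <- data.frame(gene_id = "g", variant_id = c("v3", "v4"),
                   effect_allele = "G", weight = c(1, 2))
  rA <- data.frame(z = 3, q = 0.01); rB <- data.frame(z = -3, q = 0.01)
  # disjoint nonzero sets
  oc <- overlap_and_classify(mA, mB, rA, rB)
  expect_equal(oc$n_overlap, 0L)
  expect_identical(oc$class, "both-significant-discordant")
  # identical models, concordant
  oc2 <- overlap_and_classify(mA, mA, rA, data.frame(z = 2, q = 0.03))
  expect_equal(oc2$n_overlap, 2L)
  expect_identical(oc2$class, "both-significant-concordant")
  oc3 <- overlap_and_classify(mA, mB, rA, data.frame(z = 1, q = 0.5))
  expect_identical(oc3$class, "one-significant")
  oc4 <- overlap_and_classify(mA, mB, data.frame(z = 1, q = 0.5),
                              data.frame(z = 1, q = 0.9))
  expect_identical(oc4$class, "neither")
  # gene absent in one layer
  oc5 <- overlap_and_classify(mA, mB[0, ], rA, NULL)
  expect_identical(oc5$class, "one-layer-only")
})

test_that("concordance report aggregates layers and runs the sign test", {
  co <- tiny_cohort()
  harm <- harmonize_gwas(co$geno$variants, co$gwas)
  ids <- harm$variant_id[harm$present]
  dbs <- lapply(co$omics, function(om) {
    pp <- preprocess_omics(om, co$covariates, k_pc = 5, k_sv = 5)
    train_models(co$geno, co$geno$annotation, pp$residuals,
                 gwas_variant_ids = ids, seed = 7)
  })
  db <- metawas:::new_model_db(
    do.call(rbind, lapply(dbs, `[[`, "weights")),
    do.call(rbind, lapply(dbs, `[[`, "summary")))
  ref <- list(variants = co$geno$variants, dosages = co$gwas_dosages)
  res <- association_scan(db, list(T = co$gwas), ref)
  rep <- concordance_report(res, db)
  expect_s3_class(rep, "concordance_report")
  expect_true(all(abs(rep$per_layer$rho) <= 1, na.rm = TRUE))
  expect_lte(rep$sign_test$n_positive, rep$sign_test$n_total)
  expect_equal(rep$sign_test$binom_pval,
               sign_binomial_test(rep$sign_test$n_positive,
                                  rep$sign_test$n_total))
  expect_true(all(rep$per_gene$class %in%
                    c("both-significant-concordant",
                      "both-significant-discordant",
                      "one-significant", "neither", "one-layer-only")))
})
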