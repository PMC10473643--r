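# The gene-level z-score, its LD-covariance ingredient, BH-FDR, and the
# association scan, against hand computations and matrix-form oracles.

test_that("bh_fdr matches the step-up hand computation", {
  expect_equal(bh_fdr(0.01), 0.01)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 1, 0.04)
  expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  expect_equal(bh_fdr(c(0.5, 1))[2], 1)                  # p = 1 -> q = 1
  expect_true(all(bh_fdr(rep(1, 5)) == 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ld_covariance is the reference dosage covariance, allele-aligned", {
  set.seed(41)
  n <- 5000
  x1 <- rbinom(n, 2, 0.3); x2 <- rbinom(n, 2, 0.4)
  dos <- cbind(v1 = x1, v2 = x2)
  rownames(dos) <- paste0("s", 1:n)
  model <- data.frame(gene_id = "g", variant_id = c("v1", "v2"),
                      effect_allele = "G", weight = c(1, 1))
  # one variant: Gamma = [var]
  ld1 <- ld_covariance(model[1, ], dos[, 1, drop = FALSE])
  expect_equal(ld1$Gamma[1, 1], var(x1), tolerance = 1e-12)
  # two independent variants: off-diagonal ~ 0
  ld2 <- ld_covariance(model, dos)
  expect_lt(abs(ld2$Gamma[1, 2]), 0.01)
  # allele-flipped reference column: covariance row/column sign flips
  ref <- list(variants = data.frame(variant_id = c("v1", "v2"),
                                    ref = c("G", "A"), alt = c("A", "G")),
              dosages = dos)
  ld3 <- ld_covariance(model, ref)       # v1 counted on the opposite allele
  direct <- stats::cov(cbind(2 - x1, x2))
  expect_equal(unname(ld3$Gamma), unname(direct), tolerance = 1e-12)
  expect_equal(ld3$Gamma[1, 2], -ld2$Gamma[1, 2], tolerance = 1e-12)
  # zero-variance variant retained with sigma 0 and flagged
  dos0 <- cbind(dos, v3 = rep(1, n))
  m3 <- rbind(model, data.frame(gene_id = "g", variant_id = "v3",
                                effect_allele = "G", weight = 1))
  expect_warning(ld0 <- ld_covariance(m3, dos0), "zero-variance")
  expect_true(ld0$zero_var[3])
  # no overlap is an error
  expect_error(ld_covariance(model, dos[, c(), drop = FALSE]), "no model")
})

test_that("gene z-score matches hand and matrix-form oracles", {
  # two-variant toy: w = (1,1), Gamma = [[1,.5],[.5,1]], z = (2,1)
  model <- data.frame(gene_id = "g", variant_id = c("v1", "v2"),
                      effect_allele = "G", weight = c(1, 1))
  ld <- structure(list(gene_id = "g", variant_id = c("v1", "v2"),
                       Gamma = matrix(c(1, .5, .5, 1), 2),
                       sigma = c(1, 1), zero_var = c(FALSE, FALSE)),
                  class = "ld_block_cov")
  gwas <- data.frame(variant_id = c("v1", "v2"), z = c(2, 1))
  res <- gene_zscore(model, gwas, ld)
  expect_equal(res$z, sqrt(3), tolerance = 1e-10)   # 3 / sqrt(3)
  # matrix-form oracle: w' diag(sigma) z / sqrt(w' Gamma w)
  w <- model$weight
  oracle <- drop(t(w) %*% diag(ld$sigma) %*% gwas$z /
                   sqrt(t(w) %*% ld$Gamma %*% w))
  expect_equal(res$z, oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-sqrt(3)), tolerance = 1e-12)
  # single variant with w = 1: z_g = z_1
  res1 <- gene_zscore(model[1, ], gwas,
                      structure(list(gene_id = "g", variant_id = "v1",
                                     Gamma = matrix(4), sigma = 2,
                                     zero_var = FALSE),
                                class = "ld_block_cov"))
  expect_equal(res1$z, 2, tolerance = 1e-12)
  # negating every weight negates z, leaves p unchanged
  m2 <- model; m2$weight <- -m2$weight
  res2 <- gene_zscore(m2, gwas, ld)
  expect_equal(res2$z, -res$z, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-15)
  expect_identical(res2$direction, "-")
})

test_that("z_g is invariant to a simultaneous allele flip everywhere", {
  co <- tiny_cohort()
  db <- tiny_db()
  ref <- list(variants = co$geno$variants, dosages = co$gwas_dosages)
  res <- association_scan(db, list(T = co$gwas), ref)
  # flip one variant used by the first gene in model, GWAS, and reference
  vid <- db$weights$variant_id[1]
  vflip <- co$geno$variants
  i <- match(vid, vflip$variant_id)
  tmp <- vflip$ref[i]; vflip$ref[i] <- vflip$alt[i]; vflip$alt[i] <- tmp
  db2 <- db
  j <- db2$weights$variant_id == vid
  db2$weights$weight[j] <- -db2$weights$weight[j]
  db2$weights$effect_allele[j] <- vflip$alt[i]
  gwas2 <- co$gwas
  k <- match(vid, gwas2$variant_id)
  gwas2[k, c("effect_allele", "other_allele")] <-
    gwas2[k, c("other_allele", "effect_allele")]
  gwas2$beta[k] <- -gwas2$beta[k]; gwas2$z[k] <- -gwas2$z[k]
  dos2 <- co$gwas_dosages
  dos2[, vid] <- 2 - dos2[, vid]
  res2 <- association_scan(db2, list(T = gwas2),
                           list(variants = vflip, dosages = dos2),
                           model_variants = vflip)
  expect_equal(res2$z, res$z, tolerance = 1e-10)
})

test_that("untestable and missing-variant cases are handled", {
  model <- data.frame(gene_id = "g", variant_id = c("v1", "v2"),
                      effect_allele = "G", weight = c(1, 1))
  ld <- structure(list(gene_id = "g", variant_id = c("v1", "v2"),
                       Gamma = matrix(c(1, 0, 0, 0), 2), sigma = c(1, 0),
                       zero_var = c(FALSE, TRUE)),
                  class = "ld_block_cov")
  gwas <- data.frame(variant_id = c("v1", "v2"), z = c(2, 1))
  res <- gene_zscore(model, gwas, ld)        # v2 excluded from the sum
  expect_equal(res$z, 2, tolerance = 1e-12)
  expect_equal(res$n_snps_dropped, 1L)
  # variant missing from the GWAS is dropped with a count
  res2 <- gene_zscore(model, gwas[1, , drop = FALSE],
                      structure(list(gene_id = "g",
                                     variant_id = c("v1", "v2"),
                                     Gamma = diag(2), sigma = c(1, 1),
                                     zero_var = c(FALSE, FALSE)),
                                class = "ld_block_cov"))
  expect_equal(res2$n_snps_used, 1L)
  # sigma_g = 0 -> untestable (NULL)
  ld0 <- structure(list(gene_id = "g", variant_id = "v1",
                        Gamma = matrix(0), sigma = 0, zero_var = TRUE),
                   class = "ld_block_cov")
  expect_null(gene_zscore(model[1, ], gwas, ld0))
})

test_that("association scan flags mediated genes and not null genes", {
  co <- tiny_cohort()
  db <- tiny_db()
  ref <- list(variants = co$geno$variants, dosages = co$gwas_dosages)
  res <- association_scan(db, list(T = co$gwas), ref)
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_identical(res$direction, ifelse(res$z >= 0, "+", "-"))
  # the strongest mediated gene among those with a model is detected
  a <- abs(co$truth$alpha[res$gene_id])
  strongest <- names(which.max(a))
  expect_true(res$significant[res$gene_id == strongest])
  # empty inputs give an empty table
  empty <- association_scan(
    metawas:::new_model_db(db$weights[0, ], db$summary[0, ]),
    list(T = co$gwas), ref)
  expect_equal(nrow(empty), 0L)
})

test_that("extreme associations survive p-value underflow in the report", {
  # |z| ~ 43.1 has a two-sided p ~ 1e-406, far below double range
  z <- 43.1
  lp <- metawas:::neg_log10_two_sided(z)
  expect_gt(lp, 400); expect_lt(lp, 410)
  # agreement with the direct formula where p does not underflow
  expect_equal(metawas:::neg_log10_two_sided(5),
               -log10(2 * pnorm(-5)), tolerance = 1e-10)
  res <- data.frame(gene_id = "APOE-like", layer = "protein", trait = "TC",
                    z = z, p = 0, q = 0, signed_log10_p = lp,
                    direction = "+", significant = TRUE)
  tab <- format_association_table(res)
  expect_identical(tab$TC[1], paste0(round(lp), "(+)"))
  # rounded |log10 p| with parenthesized direction, e.g. "2(-)"
  res2 <- data.frame(gene_id = c("a", "b"), layer = "protein",
                     trait = "LDL", z = c(-3.1, 1), p = c(0.002, 0.3),
                     q = c(0.01, 0.4),
                     signed_log10_p = c(-2.7, 0.5),
                     direction = c("-", "+"),
                     significant = c(TRUE, FALSE))
  tab2 <- format_association_table(res2)
  expect_identical(tab2$LDL, "3(-)")   # only significant genes listed
})
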