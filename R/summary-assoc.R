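# Gene-level association from GWAS summary statistics: the model weights are
# combined with per-variant z-scores and an LD reference covariance to give
# z_g = sum_l w_l (sigma_l / sigma_g) z_l with sigma_g^2 = w' Gamma w.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return Numeric vector of q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- p.adjust(pvals[ok], method = "BH")
  q
}

#' LD reference covariance for one model's variants
#'
#' Sample covariance of reference-panel dosages over the model's variants,
#' with the reference allele coding aligned to each model entry's effect
#' allele (a reference column counted on the opposite allele is flipped as
#' `2 - dosage`, which negates its covariance with every other variant).
#' Zero-variance variants are retained with `sigma = 0` and flagged; the
#' association statistic excludes them.
#'
#' @param model One model's weight entries (variant_id, effect_allele,
#'   weight), e.g. from [train_models()].
#' @param reference List with `variants` and `dosages` (the reference
#'   panel), or a bare dosage matrix whose columns are already aligned.
#' @return List of class `ld_block_cov`: `gene_id`, `variant_id`, `Gamma`
#'   (symmetric covariance matrix), `sigma` (per-variant dosage SD),
#'   `zero_var` (logical).
#' @export
ld_covariance <- function(model, reference) {
  ids <- model$variant_id
  if (is.matrix(reference)) {
    dos <- reference
    flip <- rep(FALSE, length(ids))
  } else {
    v <- reference$variants
    dos <- reference$dosages
    flip <- v$ref[match(ids, v$variant_id)] == model$effect_allele
    flip[is.na(flip)] <- FALSE
  }
  present <- ids %in% colnames(dos)
  if (!any(present))
    stop("no model variant found in the LD reference")
  ids <- ids[present]
  D <- dos[, ids, drop = FALSE]
  fl <- flip[present]
  if (any(fl)) D[, fl] <- 2 - D[, fl]
  Gamma <- stats::cov(D)
  sigma <- sqrt(pmax(diag(Gamma), 0))
  zero <- sigma == 0
  if (any(zero))
    warning(sum(zero), " zero-variance variant(s) in the LD reference; ",
            "excluded from the association statistic")
  structure(list(gene_id = model$gene_id[1], variant_id = ids,
                 Gamma = Gamma, sigma = sigma, zero_var = zero),
            class = "ld_block_cov")
}

# -log10 of the two-sided normal p-value, stable for large |z| (where the
# p-value itself underflows to 0).
neg_log10_two_sided <- function(z) {
  -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

#' Gene-level association z-score from summary statistics
#'
#' Combines one model's weights with harmonized GWAS z-scores and the LD
#' reference covariance:
#' `z_g = sum_l w_l (sigma_l / sigma_g) z_l`, `sigma_g^2 = w' Gamma w`,
#' with a two-sided normal p-value. Model variants missing from the GWAS or
#' with zero reference variance are dropped from the sum (the count is
#' recorded). `signed_log10_p` is computed on the log scale so it survives
#' p-values far below double precision.
#'
#' @param model One model's weight entries (variant_id, effect_allele,
#'   weight).
#' @param gwas Harmonized GWAS records for the model's variants (from
#'   [harmonize_gwas()], or any frame with variant_id, z, and optionally
#'   `present`).
#' @param ld An `ld_block_cov` from [ld_covariance()].
#' @return One-row data frame: gene_id, z, p, signed_log10_p, direction,
#'   n_snps_used, n_snps_dropped; or `NULL` (flagged untestable) when
#'   `sigma_g = 0`.
#' @export
gene_zscore <- function(model, gwas, ld) {
  m <- model[match(ld$variant_id, model$variant_id), , drop = FALSE]
  gi <- match(ld$variant_id, gwas$variant_id)
  z_l <- gwas$z[gi]
  present <- !is.na(z_l)
  if (!is.null(gwas$present)) present <- present & gwas$present[gi]
  use <- present & !ld$zero_var
  n_drop <- sum(!use)
  if (!any(use)) return(NULL)
  w <- m$weight[use]
  G <- ld$Gamma[use, use, drop = FALSE]
  sig2 <- drop(t(w) %*% G %*% w)
  if (sig2 <= 0) return(NULL)
  sigma_g <- sqrt(sig2)
  z_g <- sum(w * ld$sigma[use] * z_l[use]) / sigma_g
  p <- 2 * pnorm(-abs(z_g))
  data.frame(
    gene_id = model$gene_id[1], z = z_g, p = p,
    signed_log10_p = sign(z_g) * neg_log10_two_sided(z_g),
    direction = if (z_g >= 0) "+" else "-",
    n_snps_used = sum(use), n_snps_dropped = n_drop,
    stringsAsFactors = FALSE
  )
}

#' Association scan over a model database and one or more traits
#'
#' Runs [harmonize_gwas()], [ld_covariance()], and [gene_zscore()] for every
#' (gene, layer) model and every trait's GWAS summary, then computes
#' Benjamini-Hochberg q-values within each (layer, trait) and flags
#' significance at the FDR level.
#'
#' @param db A `model_db`.
#' @param gwas_list Named list (by trait) of GWAS summary data frames.
#' @param reference LD reference: list with `variants` + `dosages`.
#' @param model_variants Variant table for the model variants (for allele
#'   harmonization); defaults to `reference$variants`.
#' @param fdr_level Significance level on q; default 0.05.
#' @return Data frame of `AssociationResult` rows: gene_id, layer, trait,
#'   z, p, q, signed_log10_p, direction, significant.
#' @export
association_scan <- function(db, gwas_list, reference,
                             model_variants = reference$variants,
                             fdr_level = 0.05) {
  stopifnot(is.list(gwas_list), !is.null(names(gwas_list)))
  keys <- unique(db$summary[, c("gene_id", "layer")])
  rows <- list()
  for (trait in names(gwas_list)) {
    gw <- gwas_list[[trait]]
    harm_all <- harmonize_gwas(model_variants, gw)
    for (i in seq_len(nrow(keys))) {
      model <- model_entries(db, keys$gene_id[i], keys$layer[i])
      if (nrow(model) == 0) next
      ld <- tryCatch(
        suppressWarnings(ld_covariance(model, reference)),
        error = function(e) NULL)
      if (is.null(ld)) next
      res <- gene_zscore(model,
                         harm_all[match(model$variant_id,
                                        harm_all$variant_id), ,
                                  drop = FALSE],
                         ld)
      if (is.null(res)) next
      res$layer <- keys$layer[i]
      res$trait <- trait
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), layer = character(),
                      trait = character(), z = numeric(), p = numeric(),
                      q = numeric(), signed_log10_p = numeric(),
                      direction = character(), significant = logical()))
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (lay in unique(out$layer)) for (tr in unique(out$trait)) {
    i <- out$layer == lay & out$trait == tr
    if (any(i)) out$q[i] <- bh_fdr(out$p[i])
  }
  out$significant <- out$q <= fdr_level
  out[, c("gene_id", "layer", "trait", "z", "p", "q", "signed_log10_p",
          "direction", "significant", "n_snps_used", "n_snps_dropped")]
}

#' Render association results as a per-trait significance table
#'
#' One row per gene, one column per trait; each significant cell shows the
#' rounded `|log10 p|` followed by the direction in parentheses (e.g.
#' `"406(+)"`); non-significant cells show `"."`. Only genes with at least
#' one significant association are listed.
#'
#' @param results An [association_scan()] result (one layer).
#' @return Character data frame, genes x traits.
#' @export
format_association_table <- function(results) {
  traits <- unique(results$trait)
  sig_genes <- unique(results$gene_id[results$significant])
  out <- data.frame(gene_id = sig_genes, stringsAsFactors = FALSE)
  for (tr in traits) {
    cells <- rep(".", length(sig_genes))
    sub <- results[results$trait == tr & results$significant, , drop = FALSE]
    cells[match(sub$gene_id, sig_genes)] <- sprintf(
      "%d(%s)", round(abs(sub$signed_log10_p)), sub$direction)
    out[[tr]] <- cells
  }
  out
}
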