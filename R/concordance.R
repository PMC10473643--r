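# PWAS-vs-TWAS comparison suite: signed log p concordance across omic
# layers, tissue-wise sign tests, per-gene weight decomposition with allele
# orientation, and nonzero-weight overlap / direction classification.

#' Genes x contexts matrix of signed log p-values
#'
#' A context is one (layer, trait) pair. Entries are
#' `sign(z) * (-log10 p)`; missing (gene, context) pairs stay `NA`. With
#' `only_significant = TRUE` only genes with at least one significant
#' association across the contexts are kept (the display filter used for
#' cross-tissue panels).
#'
#' @param results An [association_scan()] result covering >= 2 contexts.
#' @param only_significant Keep only genes with >= 1 significant entry.
#' @return Numeric matrix, rownames = gene ids, colnames =
#'   `"<layer>|<trait>"`.
#' @export
signed_logp_matrix <- function(results, only_significant = FALSE) {
  ctx <- unique(paste(results$layer, results$trait, sep = "|"))
  if (length(ctx) < 2) stop("need at least 2 (layer, trait) contexts")
  genes <- unique(results$gene_id)
  m <- matrix(NA_real_, length(genes), length(ctx),
              dimnames = list(genes, ctx))
  key <- paste(results$layer, results$trait, sep = "|")
  m[cbind(match(results$gene_id, genes), match(key, ctx))] <-
    results$signed_log10_p
  if (only_significant) {
    sig <- unique(results$gene_id[results$significant])
    m <- m[genes %in% sig, , drop = FALSE]
  }
  m
}

#' Spearman concordance of two signed log p profiles
#'
#' Spearman rank correlation (average-rank ties) with a two-sided p-value,
#' after pairwise-complete deletion of missing entries.
#'
#' @param a,b Numeric vectors over the same genes.
#' @return List with `rho`, `pval`, `n` (complete pairs used).
#' @export
spearman_concordance <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(
    cor.test(a[ok], b[ok], method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), pval = ct$p.value, n = sum(ok))
}

#' One-sided exact binomial sign test
#'
#' Upper-tail probability `P(X >= n_positive)` for
#' `X ~ Binomial(n_total, 0.5)` — the test applied to the number of tissues
#' with positive cross-layer correlation.
#'
#' @param n_positive,n_total Counts with `0 <= n_positive <= n_total`.
#' @param alternative `"greater"` (default, upper tail) or `"two.sided"`.
#' @return The p-value.
#' @examples
#' sign_binomial_test(47, 49)  # ~2.2e-12
#' @export
sign_binomial_test <- function(n_positive, n_total,
                               alternative = c("greater", "two.sided")) {
  stopifnot(n_positive >= 0, n_positive <= n_total)
  alternative <- match.arg(alternative)
  p_up <- pbinom(n_positive - 1, n_total, 0.5, lower.tail = FALSE)
  if (alternative == "greater") return(p_up)
  stats::binom.test(n_positive, n_total, 0.5,
                    alternative = "two.sided")$p.value
}

#' Orient a model's variants so all GWAS effects are positive
#'
#' For every variant with GWAS `z < 0`, the effect allele is swapped and
#' both the weight and the z-score are negated, so all oriented z-scores are
#' `>= 0` (variants with z exactly 0 keep their orientation and are
#' flagged). Applying the function twice is the identity.
#'
#' @param model One model's weight entries (variant_id, effect_allele,
#'   weight).
#' @param gwas Harmonized GWAS records (variant_id, z; and optionally
#'   effect_allele, other_allele).
#' @param sigma Optional per-variant reference dosage SDs (named by
#'   variant id), carried through for [weight_decomposition()].
#' @return Data frame of class `oriented_model_view`: variant_id, w (oriented
#'   weight), z (oriented GWAS z >= 0), sigma, flipped, zero_z.
#' @export
orient_to_positive_gwas <- function(model, gwas, sigma = NULL) {
  z <- gwas$z[match(model$variant_id, gwas$variant_id)]
  flip <- !is.na(z) & z < 0
  out <- data.frame(
    variant_id = model$variant_id,
    w = ifelse(flip, -model$weight, model$weight),
    z = ifelse(flip, -z, z),
    sigma = if (is.null(sigma)) NA_real_
            else unname(sigma[model$variant_id]),
    flipped = flip,
    zero_z = !is.na(z) & z == 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oriented_model_view", class(out))
  out
}

#' Weighted-average decomposition of a model's oriented weights
#'
#' `WA = sum_l z_l sigma_l w_l / sum_l z_l sigma_l` over the oriented view
#' (all z >= 0). By construction WA has the same sign as, and is
#' proportional to, the gene-level association z-score:
#' `WA = z_g sigma_g / sum_l z_l sigma_l`.
#'
#' @param view An `oriented_model_view` with `sigma` available.
#' @param use_sigma Weight by `z * sigma` (default, the exact identity) or
#'   by `z` alone.
#' @return The weighted average (scalar); `NA` with a warning when the
#'   denominator is 0.
#' @export
weight_decomposition <- function(view, use_sigma = TRUE) {
  ok <- is.finite(view$z) & is.finite(view$w)
  if (use_sigma) ok <- ok & is.finite(view$sigma)
  v <- view[ok, , drop = FALSE]
  wt <- if (use_sigma) v$z * v$sigma else v$z
  den <- sum(wt)
  if (!is.finite(den) || den <= 0) {
    warning("decomposition undefined: sum of oriented z (x sigma) is not > 0")
    return(NA_real_)
  }
  sum(wt * v$w) / den
}

#' Overlap and joint-significance classification for one gene across layers
#'
#' Counts variants with nonzero weight in both layers' models and classifies
#' the gene by joint significance at `fdr_level` and direction agreement.
#'
#' @param modelA,modelB Weight entries of the same gene in two layers.
#' @param resultA,resultB One-row association results for the gene in the
#'   two layers (columns z, q); `NULL` when absent.
#' @param fdr_level FDR level; default 0.05.
#' @return List: `n_overlap`, `class` (one of
#'   `"both-significant-concordant"`, `"both-significant-discordant"`,
#'   `"one-significant"`, `"neither"`, `"one-layer-only"`).
#' @export
overlap_and_classify <- function(modelA, modelB, resultA, resultB,
                                 fdr_level = 0.05) {
  n_overlap <- length(intersect(
    modelA$variant_id[modelA$weight != 0],
    modelB$variant_id[modelB$weight != 0]))
  if (is.null(resultA) || is.null(resultB) ||
      nrow(modelA) == 0 || nrow(modelB) == 0)
    return(list(n_overlap = n_overlap, class = "one-layer-only"))
  sigA <- resultA$q <= fdr_level
  sigB <- resultB$q <= fdr_level
  cls <- if (sigA && sigB) {
    if (sign(resultA$z) == sign(resultB$z)) "both-significant-concordant"
    else "both-significant-discordant"
  } else if (sigA || sigB) "one-significant" else "neither"
  list(n_overlap = n_overlap, class = cls)
}

#' Cross-layer concordance report
#'
#' For a chosen base layer (typically the protein layer) and trait, compares
#' the signed log p profile with every other layer: Spearman rho and
#' p-value per layer, the tissue-wise sign test on the number of positive
#' correlations, and per-gene overlap/classification records against each
#' comparison layer.
#'
#' @param results An [association_scan()] result.
#' @param db The `model_db` used for the scan (for the overlap records).
#' @param base_layer Layer compared against all others; default
#'   `"protein"`.
#' @param trait Trait to compare on; default the first in `results`.
#' @param fdr_level FDR level for classification; default 0.05.
#' @return List of class `concordance_report`: `per_layer` (layer, rho,
#'   pval, n_genes), `sign_test` (n_positive, n_total, binom_pval),
#'   `per_gene` (gene_id, layer, n_overlap, class).
#' @export
concordance_report <- function(results, db = NULL, base_layer = "protein",
                               trait = results$trait[1], fdr_level = 0.05) {
  r <- results[results$trait == trait, , drop = FALSE]
  layers <- setdiff(unique(r$layer), base_layer)
  if (length(layers) == 0) stop("need at least one layer besides the base")
  base <- r[r$layer == base_layer, , drop = FALSE]
  per_layer <- data.frame(layer = layers, rho = NA_real_, pval = NA_real_,
                          n_genes = NA_integer_, stringsAsFactors = FALSE)
  per_gene <- list()
  for (k in seq_along(layers)) {
    other <- r[r$layer == layers[k], , drop = FALSE]
    genes <- intersect(base$gene_id, other$gene_id)
    if (length(genes) >= 3) {
      sc <- spearman_concordance(
        base$signed_log10_p[match(genes, base$gene_id)],
        other$signed_log10_p[match(genes, other$gene_id)])
      per_layer$rho[k] <- sc$rho
      per_layer$pval[k] <- sc$pval
      per_layer$n_genes[k] <- sc$n
    }
    if (!is.null(db)) {
      for (g in genes) {
        oc <- overlap_and_classify(
          model_entries(db, g, base_layer),
          model_entries(db, g, layers[k]),
          base[match(g, base$gene_id), , drop = FALSE],
          other[match(g, other$gene_id), , drop = FALSE],
          fdr_level)
        per_gene[[length(per_gene) + 1L]] <- data.frame(
          gene_id = g, layer = layers[k], n_overlap = oc$n_overlap,
          class = oc$class, stringsAsFactors = FALSE)
      }
    }
  }
  n_pos <- sum(per_layer$rho > 0, na.rm = TRUE)
  n_tot <- sum(!is.na(per_layer$rho))
  structure(list(
    trait = trait, base_layer = base_layer, per_layer = per_layer,
    sign_test = list(n_positive = n_pos, n_total = n_tot,
                     binom_pval = if (n_tot > 0)
                       sign_binomial_test(n_pos, n_tot) else NA_real_),
    per_gene = if (length(per_gene)) do.call(rbind, per_gene) else NULL
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report [", x$trait, "]: base =", x$base_layer, "\n")
  cat("  positive rho in", x$sign_test$n_positive, "of",
      x$sign_test$n_total, "layers (binomial p =",
      format(x$sign_test$binom_pval, digits = 2), ")\n")
  invisible(x)
}
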