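# Per-gene cis-window elastic-net prediction models with cross-validated
# performance, and the model database that bridges the training cohort and
# GWAS summary statistics.

#' Cis window around a gene body
#'
#' Closed 1-based interval extending `flank` base pairs upstream and
#' downstream of the gene body (TSS-side to TES-side bound); the start is
#' clamped at 1 and strand does not alter the window.
#'
#' @param gene One-row gene annotation (chrom, body_start, body_end).
#' @param flank Flank size in base pairs; default 1 Mb.
#' @return List with `chrom`, `start`, `end`.
#' @examples
#' cis_window(data.frame(chrom = "1", body_start = 5e6, body_end = 5.01e6))
#' @export
cis_window <- function(gene, flank = 1e6) {
  stopifnot(flank >= 0, gene$body_start <= gene$body_end)
  list(chrom = as.character(gene$chrom),
       start = max(1, gene$body_start - flank),
       end = gene$body_end + flank)
}

#' Fit one cross-validated elastic-net prediction model
#'
#' Penalized least squares with L1/L2 mixing `alpha`; the penalty strength
#' is chosen by k-fold cross-validation minimizing mean squared error.
#' Weights are reported on the per-dosage scale with the counted (alt)
#' allele as the effect allele. `cv_r2` is the squared correlation between
#' the out-of-fold predictions at the selected penalty and `y`; `cv_pval`
#' is the one-sided (positive) correlation-test p-value.
#'
#' @param X Cis dosage matrix (samples x variants, with column names).
#' @param y Omic residual vector.
#' @param alpha Elastic-net mixing parameter; default 0.5.
#' @param nfolds Cross-validation folds; default 10.
#' @param seed Seed for the fold assignment.
#' @param lambda_choice Penalty strength rule: `"1se"` (default, the
#'   strongest penalty within one standard error of the CV minimum; yields
#'   genuinely trivial models for unpredictable features) or `"min"` (the
#'   CV-minimizing penalty).
#' @return List with `weights` (named, nonzero entries only; length 0 for a
#'   trivial model), `cv_r2`, `cv_pval`, `n_train`, `foldid`. A model with
#'   no nonzero weights is "trivial".
#' @export
fit_elastic_net_cv <- function(X, y, alpha = 0.5, nfolds = 10, seed = 1L,
                               lambda_choice = c("1se", "min")) {
  lambda_choice <- match.arg(lambda_choice)
  if (sd(y) == 0) stop("response is constant")
  n <- length(y)
  stopifnot(nrow(X) == n, n >= nfolds)
  keep <- apply(X, 2, function(x) sd(x) > 0)
  if (!any(keep))
    return(list(weights = numeric(0), cv_r2 = NA_real_, cv_pval = NA_real_,
                n_train = n, foldid = NULL))
  Xk <- X[, keep, drop = FALSE]
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  if (ncol(Xk) == 1L) Xk <- cbind(Xk, `..pad..` = 0)  # glmnet needs >= 2 cols
  fit <- glmnet::cv.glmnet(Xk, y, alpha = alpha, foldid = foldid,
                           keep = TRUE, standardize = TRUE)
  lam <- if (lambda_choice == "1se") fit$lambda.1se else fit$lambda.min
  ilam <- which(fit$lambda == lam)[1]
  cf <- as.matrix(coef(fit, s = lam))
  beta <- setNames(cf[-1, 1], rownames(cf)[-1])  # drop intercept
  beta <- beta[names(beta) != "..pad.."]
  preval <- fit$fit.preval[, ilam]
  if (sd(preval) > 0) {
    ct <- cor.test(preval, y, alternative = "greater")
    cv_r2 <- unname(ct$estimate^2)
    cv_pval <- ct$p.value
  } else {
    cv_r2 <- 0; cv_pval <- 1
  }
  nz <- beta[beta != 0]
  list(weights = nz, cv_r2 = cv_r2, cv_pval = cv_pval, n_train = n,
       foldid = foldid)
}

new_model_db <- function(weights, summary, meta = list()) {
  structure(list(weights = weights, summary = summary, meta = meta),
            class = "model_db")
}

#' @export
print.model_db <- function(x, ...) {
  cat("model_db:", nrow(x$summary), "non-trivial models over",
      length(unique(x$summary$layer)), "layer(s);",
      nrow(x$weights), "weights\n")
  invisible(x)
}

#' Train cis-window prediction models for every feature of a layer
#'
#' For each gene, candidate predictors are the variants inside the gene's
#' cis window that are present in the (harmonized) GWAS; each feature's
#' residual is fit with [fit_elastic_net_cv()]. Trivial models (no nonzero
#' weight) are excluded from the database.
#'
#' @param geno List with `variants` and `dosages` (see
#'   [simulate_genotypes()] / [load_dosages()]).
#' @param annotation Gene annotation table.
#' @param residuals An [omic_matrix()] of preprocessed residuals.
#' @param gwas_variant_ids Optional character vector of variant ids present
#'   in the GWAS; candidate predictive SNPs are restricted to these.
#' @param flank Cis-window flank in bp (default 1 Mb).
#' @param alpha,nfolds,seed,lambda_choice Passed to
#'   [fit_elastic_net_cv()].
#' @return A `model_db`: `weights` (gene_id, layer, variant_id,
#'   effect_allele, weight), `summary` (gene_id, layer, cv_r2, cv_pval,
#'   n_snps_nonzero, n_train), `meta` (alpha, nfolds, seed, flank).
#' @export
train_models <- function(geno, annotation, residuals,
                         gwas_variant_ids = NULL, flank = 1e6,
                         alpha = 0.5, nfolds = 10, seed = 1L,
                         lambda_choice = "1se") {
  stopifnot(inherits(residuals, "omic_matrix"))
  v <- geno$variants
  samp <- rownames(residuals$values)
  dos <- geno$dosages[samp, , drop = FALSE]
  wlist <- list(); slist <- list()
  for (i in seq_len(nrow(residuals$feature_map))) {
    feat <- residuals$feature_map$feature_id[i]
    gene <- residuals$feature_map$gene_id[i]
    ann <- annotation[annotation$gene_id == gene, , drop = FALSE]
    if (nrow(ann) == 0) next
    win <- cis_window(ann[1, ], flank)
    cand <- v$variant_id[v$chrom == win$chrom &
                           v$pos >= win$start & v$pos <= win$end]
    if (!is.null(gwas_variant_ids))
      cand <- intersect(cand, gwas_variant_ids)
    if (length(cand) == 0) next
    fit <- fit_elastic_net_cv(dos[, cand, drop = FALSE],
                              residuals$values[, feat],
                              alpha = alpha, nfolds = nfolds, seed = seed,
                              lambda_choice = lambda_choice)
    if (length(fit$weights) == 0) next  # trivial model
    wlist[[feat]] <- data.frame(
      gene_id = gene, layer = residuals$layer,
      variant_id = names(fit$weights),
      effect_allele = v$alt[match(names(fit$weights), v$variant_id)],
      weight = unname(fit$weights), stringsAsFactors = FALSE
    )
    slist[[feat]] <- data.frame(
      gene_id = gene, layer = residuals$layer, cv_r2 = fit$cv_r2,
      cv_pval = fit$cv_pval, n_snps_nonzero = length(fit$weights),
      n_train = fit$n_train, stringsAsFactors = FALSE
    )
  }
  if (length(slist) == 0)
    return(new_model_db(
      data.frame(gene_id = character(), layer = character(),
                 variant_id = character(), effect_allele = character(),
                 weight = numeric()),
      data.frame(gene_id = character(), layer = character(),
                 cv_r2 = numeric(), cv_pval = numeric(),
                 n_snps_nonzero = integer(), n_train = integer()),
      meta = list(alpha = alpha, nfolds = nfolds, seed = seed,
                  flank = flank)))
  db <- new_model_db(do.call(rbind, wlist), do.call(rbind, slist),
                     meta = list(alpha = alpha, nfolds = nfolds,
                                 seed = seed, flank = flank,
                                 lambda_choice = lambda_choice))
  rownames(db$weights) <- rownames(db$summary) <- NULL
  db
}

#' Flag significantly predictable models at a given FDR level
#'
#' Benjamini-Hochberg q-values over all non-trivial models within each
#' layer; models with `q <= fdr_level` are flagged significant.
#'
#' @param db A `model_db`.
#' @param fdr_level FDR level; default 0.05.
#' @return The `model_db` with `q` and `significant` columns added to
#'   `summary`.
#' @export
model_significance <- function(db, fdr_level = 0.05) {
  s <- db$summary
  if (nrow(s) == 0) {
    s$q <- numeric(0)
    s$significant <- logical(0)
    db$summary <- s
    return(db)
  }
  s$q <- NA_real_
  for (lay in unique(s$layer)) {
    i <- s$layer == lay
    s$q[i] <- bh_fdr(s$cv_pval[i])
  }
  s$significant <- s$q <= fdr_level
  db$summary <- s
  db
}

#' Filter a model database on predictive p-value
#'
#' Keeps models with `cv_pval` strictly below `max_cv_pval` (the filter
#' applied to externally trained model sets, which retain only models with
#' predictive p-value less than 0.05).
#'
#' @param db A `model_db`.
#' @param max_cv_pval Strict upper bound on `cv_pval`; default 0.05.
#' @return The filtered `model_db`.
#' @export
filter_models <- function(db, max_cv_pval = 0.05) {
  keep <- db$summary$cv_pval < max_cv_pval
  s <- db$summary[keep, , drop = FALSE]
  key <- paste(db$weights$gene_id, db$weights$layer)
  db$weights <- db$weights[key %in% paste(s$gene_id, s$layer), ,
                           drop = FALSE]
  db$summary <- s
  rownames(db$weights) <- rownames(db$summary) <- NULL
  db
}

# Extract one model's weight entries from a db.
model_entries <- function(db, gene, layer) {
  db$weights[db$weights$gene_id == gene & db$weights$layer == layer, ,
             drop = FALSE]
}
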