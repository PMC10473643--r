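# Omic preprocessing: rank-based inverse normal transform, PC / surrogate
# scores, chi-squared outlier removal, and covariate residualization.

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (average-tied) ranks:
#' `qnorm((rank - offset) / (n - 2*offset + 1))`. The default `offset = 0.5`
#' gives `qnorm((rank - 0.5) / n)`; `offset = 3/8` is the Blom variant.
#' Rank order is preserved.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param offset Rank offset in `[0, 0.5]`.
#' @return Numeric vector of transformed values.
#' @examples
#' inverse_normal_transform(c(5.1, 2.0, 9.9))  # 0, -0.967, 0.967
#' @export
inverse_normal_transform <- function(values, offset = 0.5) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values[!is.na(values)])) < 2)
    stop("constant vector cannot be inverse-normal transformed")
  n <- sum(!is.na(values))
  r <- rank(values, ties.method = "average", na.last = "keep")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Top-k principal component scores of an omic matrix
#'
#' Left singular directions of the column-centered matrix, scaled to unit
#' variance per score column.
#'
#' @param om An [omic_matrix()] or a numeric samples x features matrix.
#' @param k Number of components; must be `< n_samples`.
#' @return Samples x k matrix of unit-variance scores.
#' @export
compute_pc_scores <- function(om, k = 10) {
  m <- if (inherits(om, "omic_matrix")) om$values else om
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(mc) < 1e-12)) stop("zero-variance matrix: identical samples")
  if (k >= nrow(m)) stop("k must be smaller than the number of samples")
  k <- min(k, ncol(m), nrow(m) - 1L)
  sv <- svd(mc, nu = k, nv = 0)
  if (any(sv$d[seq_len(k)] < 1e-12 * sv$d[1]))
    k <- max(1L, sum(sv$d > 1e-12 * sv$d[1]))
  sc <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  sc <- scale(sc)
  dimnames(sc) <- list(rownames(m), paste0("PC", seq_len(k)))
  sc
}

#' Surrogate values: hidden-factor scores of the covariate-adjusted residuals
#'
#' Regresses each feature on the covariates and takes the top-k left
#' singular directions of the residual matrix, unit variance per column — a
#' deterministic two-step variant of surrogate variable analysis that serves
#' the same purposes here: detecting outliers and adjusting for unobserved
#' factors.
#'
#' @param om An [omic_matrix()] or numeric matrix.
#' @param covariates Data frame or matrix of covariates (samples in rows).
#' @param k Number of surrogate values.
#' @return Samples x k matrix of unit-variance surrogate values.
#' @export
estimate_surrogate_values <- function(om, covariates, k = 10) {
  m <- if (inherits(om, "omic_matrix")) om$values else om
  X <- design_matrix(covariates, rownames(m))
  res <- ols_residuals(m, X)
  if (all(abs(res) < 1e-10))
    stop("covariates explain all variance: zero residual matrix")
  sv <- compute_pc_scores(res, k)
  colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  sv
}

#' Chi-squared outlier filter on score columns
#'
#' Per sample, `d = sum_j s_j^2` over the k standardized score columns;
#' under multivariate normality `d ~ chi-squared(k)`. Samples with upper-tail
#' p-value below `alpha` are removed.
#'
#' @param scores Samples x k numeric score matrix (standardized; columns are
#'   re-standardized defensively).
#' @param alpha Removal significance level; default 0.001.
#' @return Character vector of retained sample ids; attribute `removed`
#'   holds the removed ids.
#' @export
chisq_outlier_filter <- function(scores, alpha = 0.001) {
  s <- sweep(scores, 2, colMeans(scores))
  sds <- apply(scores, 2, sd)
  ok <- sds > 0
  s[, ok] <- sweep(s[, ok, drop = FALSE], 2, sds[ok], "/")
  s[, !ok] <- 0  # zero-variance scores contribute nothing
  d <- rowSums(s^2)
  p <- pchisq(d, df = ncol(scores), lower.tail = FALSE)
  keep <- p >= alpha
  out <- rownames(scores)[keep]
  attr(out, "removed") <- rownames(scores)[!keep]
  out
}

#' Residualize an omic matrix on covariates (and surrogates)
#'
#' Ordinary-least-squares residuals per feature against the column-bound
#' design (intercept added); residuals are orthogonal to every design
#' column.
#'
#' @param om An [omic_matrix()] or numeric matrix.
#' @param design Covariate data frame / matrix, optionally with surrogate
#'   columns bound on.
#' @return Object of the same shape as the input values with residuals.
#' @export
residualize <- function(om, design) {
  is_om <- inherits(om, "omic_matrix")
  m <- if (is_om) om$values else om
  X <- design_matrix(design, rownames(m))
  res <- ols_residuals(m, X)
  if (is_om) omic_matrix(om$layer, res, om$feature_map) else res
}

# Build a full-rank design matrix with intercept; errors naming collinear
# columns.
design_matrix <- function(design, sample_ids = NULL) {
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (!is.null(sample_ids) && !is.null(rownames(X)))
    X <- X[sample_ids, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

ols_residuals <- function(m, X) {
  qrX <- qr(X)
  qr.resid(qrX, m)
}

#' Full omic preprocessing pipeline
#'
#' Fixed order: inverse-normal transform each feature, compute top-k PC
#' scores and top-k surrogate values, remove samples failing the chi-squared
#' outlier test (p < `alpha`) on *either* score set, recompute scores on the
#' retained samples, then residualize on covariates + surrogate values.
#'
#' @param om An [omic_matrix()].
#' @param covariates Covariate data frame (samples in rows, matching `om`).
#' @param k_pc,k_sv Numbers of PC scores / surrogate values (default 10).
#' @param alpha Outlier removal level (default 0.001).
#' @param int_offset Offset for [inverse_normal_transform()].
#' @param recompute_scores Recompute PCs/surrogates on retained samples
#'   before residualization (default `TRUE`).
#' @return List: `residuals` (an [omic_matrix()] on retained samples),
#'   `retained`, `removed`, `surrogates`, and `log` (step-wise counts).
#' @export
preprocess_omics <- function(om, covariates, k_pc = 10, k_sv = 10,
                             alpha = 0.001, int_offset = 0.5,
                             recompute_scores = TRUE) {
  stopifnot(inherits(om, "omic_matrix"))
  vals <- apply(om$values, 2, inverse_normal_transform, offset = int_offset)
  rownames(vals) <- rownames(om$values)
  k_pc <- min(k_pc, nrow(vals) - 1L, ncol(vals))
  k_sv <- min(k_sv, nrow(vals) - 1L, ncol(vals))
  pcs <- compute_pc_scores(vals, k_pc)
  svs <- estimate_surrogate_values(vals, covariates, k_sv)
  keep_pc <- chisq_outlier_filter(pcs, alpha)
  keep_sv <- chisq_outlier_filter(svs, alpha)
  retained <- intersect(keep_pc, keep_sv)  # union of removals
  removed <- setdiff(rownames(vals), retained)

  vals2 <- vals[retained, , drop = FALSE]
  cov2 <- covariates[retained, , drop = FALSE]
  svs2 <- if (recompute_scores)
    estimate_surrogate_values(vals2, cov2, k_sv)
  else svs[retained, , drop = FALSE]
  design <- cbind(as.matrix(cov2), svs2)
  res <- residualize(omic_matrix(om$layer, vals2, om$feature_map), design)
  list(
    residuals = res, retained = retained, removed = removed,
    surrogates = svs2,
    log = list(layer = om$layer, n_input = nrow(om$values),
               n_removed_pc = length(attr(keep_pc, "removed")),
               n_removed_sv = length(attr(keep_sv, "removed")),
               n_removed_total = length(removed),
               n_retained = length(retained),
               k_pc = k_pc, k_sv = k_sv, alpha = alpha)
  )
}
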