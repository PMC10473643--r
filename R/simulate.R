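# Synthetic cohort generator: LD-structured genotypes, omic layers with
# sparse cis-genetic architecture, a mediated quantitative trait, and
# marginal GWAS summary statistics from an independent cohort.

# ---- latent-Gaussian LD machinery -------------------------------------------

# P(Z1 > t1, Z2 > t2) for standard bivariate normal with correlation r,
# by Gauss-Legendre quadrature over z1 on [t1, t1 + 8.5].
bvn_upper_tail <- function(r, t1, t2, nodes = 64L) {
  if (abs(r) < 1e-12) return(pnorm(t1, lower.tail = FALSE) *
                             pnorm(t2, lower.tail = FALSE))
  gl <- gauss_legendre(nodes)
  a <- t1; b <- t1 + 8.5
  z <- (b - a) / 2 * gl$x + (a + b) / 2
  w <- (b - a) / 2 * gl$w
  s <- sqrt(1 - r^2)
  sum(w * dnorm(z) * pnorm((t2 - r * z) / s, lower.tail = FALSE))
}

# Cached Gauss-Legendre nodes/weights on [-1, 1].
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # Golub-Welsch: eigen-decomposition of the Jacobi matrix
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
    cache[[key]] <<- res
    res
  }
})

# Pearson correlation between the allele indicators 1{Z1 > t1}, 1{Z2 > t2}
# induced by latent correlation r; f1, f2 are the allele frequencies.
indicator_corr <- function(r, t1, t2, f1, f2) {
  p11 <- bvn_upper_tail(r, t1, t2)
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Latent adjacent correlation needed so that the dosage correlation of two
# thresholded variants equals `target`; capped at the attainable maximum
# when the two MAFs are too far apart.
latent_r_for_target <- function(target, f1, f2) {
  if (target <= 1e-8) return(0)
  t1 <- qnorm(1 - f1); t2 <- qnorm(1 - f2)
  r_hi <- 0.9999
  c_hi <- indicator_corr(r_hi, t1, t2, f1, f2)
  if (c_hi <= target) return(r_hi)
  uniroot(function(r) indicator_corr(r, t1, t2, f1, f2) - target,
          lower = 0, upper = r_hi, tol = 1e-6)$root
}

# ---- variant / gene layout --------------------------------------------------

GENE_SPACING <- 3e6
GENE_BODY_LEN <- 2e4
CIS_FLANK_DEFAULT <- 1e6

# Deterministic gene/variant layout: positions, target MAFs, thresholds and
# calibrated latent adjacent correlations. Shared by every cohort drawn from
# the same configuration, so training and GWAS cohorts see identical variants.
sim_layout <- function(cfg) {
  set.seed(sim_seed(cfg, 1L))
  p <- cfg$n_variants_per_gene
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  body_start <- (seq_len(cfg$n_genes) - 1L) * GENE_SPACING + 1.5e6
  body_end <- body_start + GENE_BODY_LEN
  annotation <- data.frame(
    gene_id = genes, chrom = "1",
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  alleles <- c("A", "C", "G", "T")
  blocks <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    win <- c(max(1, body_start[g] - CIS_FLANK_DEFAULT),
             body_end[g] + CIS_FLANK_DEFAULT)
    pos <- sort(sample(seq(win[1], win[2]), p))
    maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
    ref <- sample(alleles, p, replace = TRUE)
    alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1L), "")
    r_lat <- if (p > 1)
      vapply(seq_len(p - 1), function(l)
        latent_r_for_target(cfg$ld_decay, maf[l], maf[l + 1]), 0.0)
    else numeric(0)
    blocks[[g]] <- list(
      gene_id = genes[g],
      variant_id = sprintf("snp_1_%d", pos),
      pos = pos, maf = maf, ref = ref, alt = alt,
      threshold = qnorm(1 - maf), r_latent = r_lat
    )
  }
  variants <- do.call(rbind, lapply(blocks, function(b)
    data.frame(variant_id = b$variant_id, chrom = "1", pos = b$pos,
               ref = b$ref, alt = b$alt, maf = b$maf, gene_id = b$gene_id,
               stringsAsFactors = FALSE)))
  rownames(variants) <- NULL
  list(cfg = cfg, annotation = annotation, variants = variants,
       blocks = blocks)
}

# Draw allele-count dosages for one cohort from a layout. Two independent
# latent AR(1) haplotypes per sample, thresholded at the MAF quantile.
draw_dosages <- function(layout, n_samples, seed, sample_prefix = "S") {
  set.seed(seed)
  blocks <- layout$blocks
  p <- length(blocks[[1]]$pos)
  total <- length(blocks) * p
  dos <- matrix(0L, nrow = n_samples, ncol = total)
  col <- 0L
  for (b in blocks) {
    # latent chains for both haplotypes at once: n_samples x 2 per variant
    z <- matrix(rnorm(n_samples * 2L), n_samples, 2L)
    alle <- (z > b$threshold[1])
    dos[, col + 1L] <- alle[, 1L] + alle[, 2L]
    if (p > 1) for (l in 2:p) {
      r <- b$r_latent[l - 1L]
      z <- r * z + sqrt(1 - r^2) * matrix(rnorm(n_samples * 2L), n_samples, 2L)
      alle <- (z > b$threshold[l])
      dos[, col + l] <- alle[, 1L] + alle[, 2L]
    }
    col <- col + p
  }
  dimnames(dos) <- list(sprintf("%s%05d", sample_prefix, seq_len(n_samples)),
                        layout$variants$variant_id)
  dos
}

# ---- public simulator operations -------------------------------------------

#' Simulate LD-structured genotype dosages
#'
#' Generates one independent LD block per gene. Within a block the latent
#' haplotype process is first-order autoregressive; the latent adjacent
#' correlation is calibrated so the realized *dosage* correlation of adjacent
#' variants matches `cfg$ld_decay`. Variant positions fall inside each gene's
#' +/- 1 Mb cis window; per-variant minor allele frequencies are drawn from
#' `cfg$maf_range`.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Cohort size; defaults to `cfg$n_train_samples`.
#' @param cohort Seed stream label: `"train"` or `"gwas"` cohorts are
#'   disjoint draws from the same generative law.
#' @return A list with `variants` (variant table: variant_id, chrom, pos,
#'   ref, alt, maf, gene_id — `maf` is the realized cohort MAF),
#'   `annotation` (gene_id, chrom, body_start, body_end, strand), and
#'   `dosages` (samples x variants integer matrix of alt-allele counts).
#' @examples
#' g <- simulate_genotypes(sim_config(n_genes = 2, n_train_samples = 50,
#'                                    n_variants_per_gene = 5))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(cfg, n_samples = cfg$n_train_samples,
                               cohort = c("train", "gwas")) {
  validate_sim_config(cfg)
  if (cfg$n_variants_per_gene < 1L) stop("n_variants_per_gene must be >= 1")
  cohort <- match.arg(cohort)
  layout <- sim_layout(cfg)
  seed <- sim_seed(cfg, if (cohort == "train") 2L else 3L)
  prefix <- if (cohort == "train") "S" else "W"
  dos <- draw_dosages(layout, n_samples, seed, prefix)
  variants <- layout$variants
  af <- colMeans(dos) / 2
  variants$maf <- pmin(af, 1 - af)
  list(variants = variants, annotation = layout$annotation,
       dosages = dos, layout = layout)
}

#' Simulate covariates for a cohort
#'
#' Continuous (age-like, two genetic-PC-like) and binary one-hot (sex,
#' medication-use) columns, emulating the covariate table adjusted for before
#' model training.
#'
#' @param cfg A [sim_config()].
#' @param sample_ids Character vector of sample ids (rows).
#' @return Data frame with rownames = sample ids, numeric columns only.
#' @export
simulate_covariates <- function(cfg, sample_ids) {
  set.seed(sim_seed(cfg, 4L))
  n <- length(sample_ids)
  cov <- data.frame(
    age = rnorm(n, 60, 8),
    sex = rbinom(n, 1L, 0.5),
    medication = rbinom(n, 1L, 0.3),
    pc1 = rnorm(n),
    pc2 = rnorm(n),
    row.names = sample_ids
  )
  cov
}

#' Simulate omic layers with sparse cis-genetic architecture
#'
#' Each feature follows `y = X b + C g + H d + e`, where `X b` is the sparse
#' cis-genetic component scaled so its in-sample variance share equals
#' `cfg$cis_h2`, `C` are the known covariates, `H` are hidden factors shared
#' across features, and the total variance is 1. One protein layer and
#' `cfg$n_tissues` expression layers are produced; the causal variant set is
#' shared across layers and per-gene effect vectors of protein vs each
#' expression layer are drawn with correlation `cfg$cross_layer_effect_corr`.
#'
#' @param cfg A [sim_config()].
#' @param geno Result of [simulate_genotypes()] for the training cohort.
#' @param covariates Covariate data frame for the same samples.
#' @return A list with `omics` (named list of `omic_matrix` objects, one per
#'   layer) and `truth` (a `sim_truth` carrying causal ids, per-layer
#'   per-dosage effect vectors, mediation coefficients `alpha`, and the
#'   hidden-factor matrix).
#' @export
simulate_omics <- function(cfg, geno, covariates) {
  validate_sim_config(cfg)
  if (cfg$cis_h2 >= 1) stop("cis_h2 must be < 1")
  if (!identical(rownames(geno$dosages), rownames(covariates)))
    stop("genotypes and covariates must share the same sample set")
  set.seed(sim_seed(cfg, 5L))
  n <- nrow(geno$dosages)
  genes <- geno$annotation$gene_id
  layers <- c("protein", if (cfg$n_tissues > 0)
    paste0("expression:tissue", seq_len(cfg$n_tissues)))

  hid_var <- if (cfg$n_hidden_factors > 0L) cfg$hidden_var else 0
  noise_var <- 1 - cfg$cis_h2 - cfg$covariate_var - hid_var
  H <- if (cfg$n_hidden_factors > 0L)
    matrix(rnorm(n * cfg$n_hidden_factors), n) else NULL
  Cm <- scale(as.matrix(covariates))

  rho <- cfg$cross_layer_effect_corr
  causal <- list(); effects <- list()
  for (lay in layers) effects[[lay]] <- list()
  values <- lapply(layers, function(l) matrix(0, n, length(genes)))
  names(values) <- layers

  for (gi in seq_along(genes)) {
    b <- geno$layout$blocks[[gi]]
    idx <- match(b$variant_id, colnames(geno$dosages))
    ci <- sort(sample(seq_along(idx), cfg$n_causal_per_gene))
    causal[[genes[gi]]] <- b$variant_id[ci]
    b_prot <- rnorm(cfg$n_causal_per_gene)
    Xc <- geno$dosages[, idx[ci], drop = FALSE]
    for (lay in layers) {
      b_raw <- if (lay == "protein") b_prot else
        rho * b_prot + sqrt(1 - rho^2) * rnorm(cfg$n_causal_per_gene)
      gcomp <- drop(Xc %*% b_raw)
      s_g <- if (cfg$cis_h2 > 0 && sd(gcomp) > 0)
        sqrt(cfg$cis_h2) / sd(gcomp) else 0
      w <- setNames(s_g * b_raw, b$variant_id[ci])
      effects[[lay]][[genes[gi]]] <- w
      y <- gcomp * s_g
      if (cfg$covariate_var > 0) {
        ce <- drop(Cm %*% rnorm(ncol(Cm)))
        y <- y + ce * sqrt(cfg$covariate_var) / sd(ce)
      }
      if (!is.null(H)) {
        he <- drop(H %*% rnorm(ncol(H)))
        y <- y + he * sqrt(hid_var) / sd(he)
      }
      e <- rnorm(n)
      y <- y + e * sqrt(noise_var) / sd(e)
      values[[lay]][, gi] <- y
    }
  }

  n_null <- round(cfg$prop_null_genes * cfg$n_genes)
  null_genes <- if (n_null > 0) sort(sample(genes, n_null)) else character(0)
  alpha <- setNames(rnorm(length(genes), 0, cfg$mediation_effect_sd), genes)
  alpha[null_genes] <- 0

  omics <- lapply(layers, function(lay) {
    feat <- if (lay == "protein") paste0("P_", genes) else genes
    m <- values[[lay]]
    dimnames(m) <- list(rownames(geno$dosages), feat)
    omic_matrix(lay, m, data.frame(feature_id = feat, gene_id = genes,
                                   stringsAsFactors = FALSE))
  })
  names(omics) <- layers

  truth <- structure(list(
    layout = geno$layout, causal = causal, effects = effects,
    alpha = alpha, null_genes = null_genes, hidden = H,
    mediating_layer = "protein"
  ), class = "sim_truth")
  list(omics = omics, truth = truth)
}

#' Simulate a mediated trait and marginal GWAS summary statistics
#'
#' Draws an independent GWAS cohort from the same genotype law, builds the
#' trait `T = sum_g alpha_g m_g + e` (with `m_g` the gene's genetically
#' determined omic component on the mediating layer, and `T` standardized to
#' variance 1), and computes per-variant marginal ordinary-least-squares
#' effect sizes and standard errors.
#'
#' @param cfg A [sim_config()].
#' @param truth A `sim_truth` from [simulate_omics()].
#' @param alpha Optional named override of the mediation coefficients.
#' @param trait_name Label for the trait column.
#' @param keep_dosages Keep the GWAS-cohort dosage matrix in the result
#'   (needed for individual-level oracle checks and for using this cohort as
#'   the LD reference).
#' @return A list with `trait` (data frame sample_id, value), `gwas` (GWAS
#'   summary data frame: variant_id, chrom, pos, effect_allele, other_allele,
#'   beta, se, z, n), and optionally `dosages`.
#' @export
simulate_trait_and_gwas <- function(cfg, truth, alpha = NULL,
                                    trait_name = "trait",
                                    keep_dosages = TRUE) {
  validate_sim_config(cfg)
  layout <- truth$layout
  n <- cfg$n_gwas_samples
  dos <- draw_dosages(layout, n, sim_seed(cfg, 3L), "W")
  set.seed(sim_seed(cfg, 6L))
  if (is.null(alpha)) alpha <- truth$alpha
  genes <- layout$annotation$gene_id
  tvec <- numeric(n)
  eff <- truth$effects[[truth$mediating_layer]]
  for (g in genes) {
    if (is.na(alpha[g]) || alpha[g] == 0) next
    w <- eff[[g]]
    tvec <- tvec + alpha[g] * drop(dos[, names(w), drop = FALSE] %*% w)
  }
  gvar <- var(tvec)
  if (gvar < 1) {
    e <- rnorm(n)
    tvec <- tvec + e * sqrt(1 - gvar) / sd(e)
  }
  tvec <- drop(scale(tvec))

  # vectorized per-variant marginal OLS
  xm <- colMeans(dos)
  sxx <- colSums(dos^2) - n * xm^2
  sxy <- drop(crossprod(dos, tvec))  # tvec is centered
  syy <- sum(tvec^2)
  ok <- sxx > 0
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  ssr <- pmax(syy - beta * sxy, 0)
  se <- ifelse(ok, sqrt(ssr / (n - 2) / sxx), NA_real_)
  v <- layout$variants
  gwas <- data.frame(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    beta = beta, se = se, z = beta / se, n = n,
    stringsAsFactors = FALSE
  )
  gwas <- gwas[ok & is.finite(gwas$se) & gwas$se > 0, ]
  rownames(gwas) <- NULL
  out <- list(trait = data.frame(sample_id = rownames(dos), value = tvec,
                                 stringsAsFactors = FALSE),
              trait_name = trait_name, gwas = gwas)
  if (keep_dosages) out$dosages <- dos
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()], [simulate_omics()], and
#' [simulate_trait_and_gwas()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @param keep_gwas_dosages Passed to [simulate_trait_and_gwas()].
#' @return A list with `geno`, `covariates`, `omics`, `truth`, `trait`,
#'   `gwas`, and (optionally) `gwas_dosages`.
#' @export
simulate_cohort <- function(cfg, keep_gwas_dosages = TRUE) {
  geno <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg, rownames(geno$dosages))
  om <- simulate_omics(cfg, geno, cov)
  tg <- simulate_trait_and_gwas(cfg, om$truth,
                                keep_dosages = keep_gwas_dosages)
  list(geno = geno, covariates = cov, omics = om$omics, truth = om$truth,
       trait = tg$trait, gwas = tg$gwas, gwas_dosages = tg$dosages)
}

#' Omic matrix container
#'
#' A samples x features matrix for one omic layer, with a feature-to-gene
#' map. Features mapping to zero or multiple genes are not representable:
#' the map must be one gene per feature.
#'
#' @param layer Layer label, e.g. `"protein"` or `"expression:tissue1"`.
#' @param values Numeric matrix, samples x features, with dimnames.
#' @param feature_map Data frame with columns `feature_id`, `gene_id`.
#' @return An `omic_matrix` object.
#' @export
omic_matrix <- function(layer, values, feature_map) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !is.null(rownames(values)),
            all(c("feature_id", "gene_id") %in% names(feature_map)))
  if (anyDuplicated(feature_map$feature_id))
    stop("feature_map has duplicated feature ids")
  if (!all(colnames(values) %in% feature_map$feature_id))
    stop("every column of 'values' must appear in 'feature_map'")
  structure(list(layer = layer, values = values,
                 feature_map = feature_map[
                   match(colnames(values), feature_map$feature_id), ,
                   drop = FALSE]),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat("omic_matrix [", x$layer, "]: ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}
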