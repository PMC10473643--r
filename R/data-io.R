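# Readers/writers for the pipeline's external formats and the allele
# harmonization contract between GWAS summary statistics and model variants.

#' Write genotype dosages to VCF
#'
#' Emits a VCFv4.2 file with `GT:DS` per sample; `DS` carries the expected
#' alternate-allele count. Read back with [load_dosages()].
#'
#' @param variants Variant table (variant_id, chrom, pos, ref, alt).
#' @param dosages Samples x variants numeric matrix in `[0, 2]`.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf_dosage <- function(variants, dosages, path) {
  stopifnot(all(colnames(dosages) == variants$variant_id))
  samples <- rownames(dosages)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_of <- function(d) ifelse(d < 0.5, "0/0", ifelse(d < 1.5, "0/1", "1/1"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    d <- dosages[, i]
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT:DS",
            paste0(gt_of(d), ":", format(d, trim = TRUE, digits = 6))),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load genotype dosages from VCF with a MAF filter
#'
#' Reads a VCF via \pkg{vcfR}; uses the `DS` FORMAT field when present,
#' otherwise converts hard `GT` genotypes to alt-allele counts. Variants with
#' minor allele frequency less than or equal to `maf_threshold` are removed
#' (the published filter is "MAF of 0.05 or less"). Residual missing entries
#' are mean-imputed per variant.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param maf_threshold Variants with MAF `<=` this are dropped; default 0.05.
#' @return List with `variants` (variant_id, chrom, pos, ref, alt, maf) and
#'   `dosages` (samples x variants matrix).
#' @export
load_dosages <- function(vcf_path, maf_threshold = 0.05) {
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", vcf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  has_ds <- any(grepl("DS", vcf@gt[, 1]))
  if (has_ds) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, 2, function(col) {
      a <- gsub("\\|", "/", col)
      vapply(strsplit(a, "/"), function(x)
        if (anyNA(x) || any(x == ".")) NA_real_
        else sum(as.numeric(x) > 0), 0.0)
    })
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(dos) <- ids
  dos <- t(dos)  # samples x variants
  # per-variant mean imputation of missing dosages
  na_cols <- which(colSums(is.na(dos)) > 0)
  for (j in na_cols) {
    m <- mean(dos[, j], na.rm = TRUE)
    dos[is.na(dos[, j]), j] <- if (is.nan(m)) 0 else m
  }
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > maf_threshold
  if (!any(keep))
    stop("all variants removed by the MAF filter (threshold ",
         maf_threshold, ")")
  variants <- data.frame(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = maf, stringsAsFactors = FALSE
  )[keep, ]
  rownames(variants) <- NULL
  list(variants = variants, dosages = dos[, keep, drop = FALSE])
}

#' Load an omic matrix from a tab-separated table
#'
#' Expects samples in rows (first column = sample id) and features in
#' columns. Features mapping to zero or more than one gene in
#' `feature_gene_map` are dropped (multi-gene aptamer targets are removed in
#' the published preprocessing); the number dropped is reported via a
#' message and an attribute.
#'
#' @param table_path Tab-separated file, samples x features.
#' @param feature_gene_map Data frame with columns `feature_id`, `gene_id`.
#' @param layer Layer label for the result.
#' @return An [omic_matrix()]; attribute `n_dropped` counts removed features.
#' @export
load_omics <- function(table_path, feature_gene_map, layer = "protein") {
  tab <- read.table(table_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in '", table_path, "'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  counts <- table(feature_gene_map$feature_id)
  multi <- names(counts)[counts > 1]
  ok_map <- feature_gene_map[!feature_gene_map$feature_id %in% multi, ,
                             drop = FALSE]
  keep <- colnames(m) %in% ok_map$feature_id
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " features dropped (unmapped or multi-gene)")
  om <- omic_matrix(layer, m[, keep, drop = FALSE], ok_map)
  attr(om, "n_dropped") <- n_dropped
  om
}

#' @rdname load_omics
#' @param om An [omic_matrix()] to write.
#' @param path Output path.
#' @export
write_omics <- function(om, path) {
  df <- data.frame(sample_id = rownames(om$values), om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generic tab-separated table IO
#'
#' Thin wrappers standardizing the pipeline's table format (header, tab
#' separator, no quoting, full precision).
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

# matching key robust to id differences between cohort and GWAS
variant_key <- function(chrom, pos, a1, a2) {
  swap <- a1 > a2
  paste0(chrom, ":", pos, ":",
         ifelse(swap, a2, a1), ":", ifelse(swap, a1, a2))
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize GWAS summary statistics to model variants
#'
#' Matches GWAS records to model variants by chrom:pos:sorted-allele-pair.
#' Where the GWAS effect/other alleles are swapped relative to the model's
#' effect (alt) allele, `beta` and `z` are negated. Records whose alleles do
#' not match either orientation are dropped; model variants absent from the
#' GWAS are flagged `present = FALSE` so training can exclude them.
#' Applying the function twice is an involution on allele swaps.
#'
#' @param model_variants Variant table (variant_id, chrom, pos, ref, alt).
#' @param gwas GWAS summary data frame (chrom, pos, effect_allele,
#'   other_allele, beta, se, and optionally z, n).
#' @param drop_palindromic Drop strand-ambiguous A/T and C/G variants
#'   (default `FALSE`: synthetic and strand-aligned data need exact matching
#'   only).
#' @return Data frame with one row per model variant: variant_id,
#'   effect_allele (the model's alt), beta, se, z, n, `present`;
#'   attribute `n_dropped` counts allele-mismatched or palindromic records.
#' @export
harmonize_gwas <- function(model_variants, gwas, drop_palindromic = FALSE) {
  stopifnot(all(c("chrom", "pos", "effect_allele", "other_allele",
                  "beta", "se") %in% names(gwas)))
  if (is.null(gwas$z)) gwas$z <- gwas$beta / gwas$se
  g <- gwas
  n_drop <- 0L
  if (drop_palindromic) {
    pal <- is_palindromic(g$effect_allele, g$other_allele)
    n_drop <- n_drop + sum(pal)
    g <- g[!pal, , drop = FALSE]
  }
  gk <- variant_key(g$chrom, g$pos, g$effect_allele, g$other_allele)
  mk <- variant_key(model_variants$chrom, model_variants$pos,
                    model_variants$ref, model_variants$alt)
  idx <- match(mk, gk)
  out <- data.frame(
    variant_id = model_variants$variant_id,
    effect_allele = model_variants$alt,
    beta = NA_real_, se = NA_real_, z = NA_real_, n = NA_real_,
    present = !is.na(idx),
    stringsAsFactors = FALSE
  )
  hit <- which(!is.na(idx))
  if (length(hit)) {
    gi <- idx[hit]
    same <- g$effect_allele[gi] == model_variants$alt[hit] &
      g$other_allele[gi] == model_variants$ref[hit]
    swapped <- g$effect_allele[gi] == model_variants$ref[hit] &
      g$other_allele[gi] == model_variants$alt[hit]
    sgn <- ifelse(same, 1, ifelse(swapped, -1, NA))
    mism <- is.na(sgn)
    n_drop <- n_drop + sum(mism)
    out$present[hit[mism]] <- FALSE
    okh <- hit[!mism]
    sg <- sgn[!mism]; gio <- gi[!mism]
    out$beta[okh] <- sg * g$beta[gio]
    out$se[okh] <- g$se[gio]
    out$z[okh] <- sg * g$z[gio]
    if (!is.null(g$n)) out$n[okh] <- g$n[gio]
  }
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write / read a prediction-model database
#'
#' The on-disk layout mirrors the conventional prediction-model-database
#' format: a weight table (gene_id, layer, variant_id, effect_allele,
#' weight) and a per-gene summary table (gene_id, layer, cv_r2, cv_pval,
#' n_snps_nonzero, n_train), both tab-separated, so third-party model sets
#' in the same layout can be imported.
#'
#' @param db A `model_db` (see [train_models()]).
#' @param weights_path,summary_path File paths for the two tables.
#' @return `write_model_db()` returns the paths invisibly; `read_model_db()`
#'   returns a `model_db`.
#' @export
write_model_db <- function(db, weights_path, summary_path) {
  write_tsv_table(db$weights, weights_path)
  write_tsv_table(db$summary, summary_path)
  invisible(c(weights_path, summary_path))
}

#' @rdname write_model_db
#' @export
read_model_db <- function(weights_path, summary_path) {
  w <- read_tsv_table(weights_path)
  s <- read_tsv_table(summary_path)
  new_model_db(w, s)
}
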