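#' Construct a genotype matrix
#'
#' Container for effect-allele dosages with per-variant metadata. Dosages are
#' counts of the coded (effect) allele in `[0, 2]`; missing genotypes are `NA`.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param variants Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele` and optionally `frequency` (effect-allele frequency) and
#'   `block_id` (LD block label). One row per column of `dosages`.
#' @param sample_ids Character vector of unique sample identifiers; defaults to
#'   the rownames of `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `sample_ids`. The missing mask is `is.na()` of
#'   the dosage matrix.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("length(sample_ids) must equal nrow(dosages)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != ncol(dosages)) {
    stop("nrow(variants) must equal ncol(dosages)")
  }
  needed <- c("variant_id", "effect_allele", "other_allele")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols)) {
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant ids")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  if (is.null(variants$frequency)) {
    variants$frequency <- colMeans(dosages, na.rm = TRUE) / 2
  }
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      sum(is.na(x$dosages)), "missing genotypes\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

## subset by variant index, keeping metadata in step
subset_variants <- function(gm, keep) {
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE],
                  gm$sample_ids)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF `GT` fields are mapped to counts of the ALT allele, which becomes the
#' coded effect allele (`ALT`-as-effect convention). Missing genotypes
#' (`./.`) are flagged as `NA`, never imputed at this stage. The TSV format is
#' the one written by [write_genotypes()]: a `sample_id` column followed by one
#' dosage column per variant, with an optional sidecar `<path>.variants.tsv`
#' holding allele metadata.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                       dimnames = list(NULL, names(gt)))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))
    ids <- fix[, "ID"]
    bad <- which(is.na(ids) | ids == ".")
    if (length(bad)) ids[bad] <- paste0("var", bad)
    # dosage = number of ALT alleles in the GT string
    count_alt <- function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    dos <- t(matrix(vapply(gt, count_alt, numeric(1)),
                    nrow = nrow(gt), ncol = ncol(gt)))
    sample_ids <- colnames(gt)
    if (anyDuplicated(sample_ids)) stop("duplicated sample ids in VCF")
    variants <- data.frame(variant_id = ids,
                           effect_allele = fix[, "ALT"],
                           other_allele = fix[, "REF"],
                           stringsAsFactors = FALSE)
    return(genotype_matrix(dos, variants, sample_ids))
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") {
    stop("dosage TSV must have a leading 'sample_id' column (", path, ")")
  }
  sample_ids <- as.character(tab$sample_id)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  meta_path <- paste0(path, ".variants.tsv")
  if (file.exists(meta_path)) {
    variants <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(variant_id = colnames(dos),
                           effect_allele = NA_character_,
                           other_allele = NA_character_,
                           stringsAsFactors = FALSE)
  }
  genotype_matrix(dos, variants, sample_ids)
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits a minimal VCF 4.2 with `GT` only; dosages 0/1/2 become
#' `0/0`, `0/1`, `1/1` with the effect allele as ALT, and `NA` becomes `./.`.
#' Non-integer dosages cannot be represented in VCF and are rejected. The TSV
#' writer also emits `<path>.variants.tsv` with the allele metadata so that a
#' round trip preserves the object.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(sample_id = gm$sample_ids, gm$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gm$variants, paste0(path, ".variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  d <- gm$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE)) {
    stop("VCF output requires integer dosages; use format = 'tsv'")
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  for (j in seq_len(ncol(d))) {
    gts <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(round(d[, j]))])
    rec <- paste(c("1", j, gm$variants$variant_id[j],
                   gm$variants$other_allele[j], gm$variants$effect_allele[j],
                   ".", "PASS", ".", "GT", gts), collapse = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}

#' Filter variants by minor allele frequency
#'
#' Retains variants whose minor allele frequency, computed from the observed
#' dosages, is strictly greater than `threshold` (the common `MAF > 0.05`
#' convention: the boundary itself is excluded).
#'
#' @param gm A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return Filtered [genotype_matrix()].
#' @export
maf_filter <- function(gm, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  f <- colMeans(gm$dosages, na.rm = TRUE) / 2
  # rounding guards the strict boundary against binary representation noise
  maf <- round(pmin(f, 1 - f), 12)
  subset_variants(gm, which(maf > threshold))
}

#' Prune variants in approximate linkage disequilibrium
#'
#' Greedy left-to-right scan over sliding windows: within each window, when a
#' retained earlier variant and a later variant have squared Pearson dosage
#' correlation at or above `r2_threshold`, the later variant is dropped.
#' Deterministic for a fixed input order. Zero-variance variants are dropped
#' up front with a warning (their correlation is undefined).
#'
#' @param gm A [genotype_matrix()].
#' @param r2_threshold Squared-correlation threshold in `(0, 1]`.
#' @param window Window size in variants.
#' @param step Offset between successive windows.
#' @return Pruned [genotype_matrix()], with pruning parameters recorded in
#'   `attr(, "prune_params")`.
#' @export
ld_prune <- function(gm, r2_threshold = 0.1, window = 50, step = 5) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must be in (0, 1]")
  }
  v <- apply(gm$dosages, 2, stats::var, na.rm = TRUE)
  if (any(v == 0 | is.na(v))) {
    warning(sum(v == 0 | is.na(v)), " zero-variance variants dropped before pruning")
    gm <- subset_variants(gm, which(v > 0 & !is.na(v)))
  }
  m <- ncol(gm$dosages)
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1, max(1, m - window + 1), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      stats::cor(gm$dosages[, idx, drop = FALSE],
                 use = "pairwise.complete.obs")^2)
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (!is.na(r2[a, b]) && r2[a, b] >= r2_threshold) keep[idx[b]] <- FALSE
      }
    }
  }
  out <- subset_variants(gm, which(keep))
  attr(out, "prune_params") <- list(r2_threshold = r2_threshold,
                                    window = window, step = step)
  out
}

#' Principal components of a genotype matrix
#'
#' Ancestry PCA in the usual GWAS sense: variants are column-standardized
#' (after per-variant mean imputation of missing dosages), and the leading
#' components of the sample covariance are returned. Scores have zero mean;
#' each component's sign is fixed by making its largest-magnitude loading
#' positive, so results do not depend on the eigensolver's sign convention.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return; must not exceed the
#'   matrix rank `min(n_samples - 1, n_variants)`.
#' @return List with `scores` (samples x components, columns `PC1..PCk`),
#'   `loadings`, and `explained_variance` (eigenvalues, decreasing).
#' @export
pca_components <- function(gm, n_components) {
  X <- gm$dosages
  for (j in seq_len(ncol(X))) {        # mean-impute for PCA only
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance variants excluded from PCA")
    X <- X[, ok, drop = FALSE]
    sds <- sds[ok]
  }
  X <- scale(X, center = TRUE, scale = sds)
  rk <- min(nrow(X) - 1L, ncol(X))
  if (n_components > rk) {
    stop("n_components (", n_components, ") exceeds matrix rank (", rk, ")")
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- gm$sample_ids
  list(scores = scores, loadings = loadings,
       explained_variance = pc$sdev[seq_len(n_components)]^2)
}
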