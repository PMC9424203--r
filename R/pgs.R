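#' Read and write polygenic-score weight tables
#'
#' Weight tables are TSVs with PGS-Catalog-compatible column names:
#' `variant_id`, `effect_allele`, `other_allele`, `effect_weight`. The
#' provenance of the weights (`"marginal"` GWAS estimates or `"sblup"`
#' re-estimates) is carried in `attr(, "provenance")`.
#'
#' @param path File path.
#' @return `read_weights()` returns the weights data frame; `write_weights()`
#'   returns `path` invisibly.
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("variant_id", "effect_allele", "other_allele", "effect_weight")
  if (!all(needed %in% names(w))) {
    stop("weights TSV must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(w$variant_id)) stop("duplicated variant ids in weights")
  if (any(!is.finite(w$effect_weight))) stop("non-finite weights")
  attr(w, "provenance") <- attr(w, "provenance") %||% "marginal"
  w
}

#' @rdname read_weights
#' @param weights Weights data frame.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GWAS summary metadata
#'
#' Holds the three quantities that govern summary-statistic BLUP shrinkage
#' and expected PGS accuracy: the SNP heritability `h2_snp`, the number of
#' independent variants `M`, and the discovery sample size `N`.
#'
#' @param h2_snp SNP heritability in `(0, 1)`.
#' @param M Number of independent variants (> 0).
#' @param N Discovery GWAS sample size (> 0).
#' @return List of class `gwas_meta`.
#' @export
gwas_meta <- function(h2_snp, M, N) {
  if (h2_snp <= 0 || h2_snp >= 1) stop("h2_snp must be in (0, 1)")
  if (M <= 0 || N <= 0) stop("M and N must be positive")
  structure(list(h2_snp = h2_snp, M = M, N = N), class = "gwas_meta")
}

#' SBLUP re-estimation of marginal GWAS weights
#'
#' Joint (best-linear-unbiased-prediction) effect sizes from marginal ones,
#' accounting for linkage disequilibrium: per LD block with correlation
#' matrix `R`, solves `(R + kappa I) b = beta_marginal` with ridge penalty
#' `kappa = lambda / N`, `lambda = M (1 / h2_snp - 1)`. This is the
#' summary-statistic form of individual-level ridge regression with penalty
#' `lambda` on standardized genotypes; with `R = I` it reduces to uniform
#' shrinkage `beta / (1 + kappa)`.
#'
#' @param marginal Weights data frame (see [read_weights()]).
#' @param ld_blocks Named list of per-block correlation matrices; each must be
#'   symmetric with dimnames naming the variants, and every variant in
#'   `marginal` must belong to exactly one block.
#' @param meta A [gwas_meta()].
#' @return Weights data frame with re-estimated `effect_weight` and
#'   provenance `"sblup"`.
#' @export
sblup_reweight <- function(marginal, ld_blocks, meta) {
  stopifnot(inherits(meta, "gwas_meta"))
  kappa <- meta$M * (1 / meta$h2_snp - 1) / meta$N
  block_vars <- unlist(lapply(ld_blocks, colnames), use.names = FALSE)
  if (anyDuplicated(block_vars)) stop("a variant appears in more than one LD block")
  missing_v <- setdiff(marginal$variant_id, block_vars)
  if (length(missing_v)) {
    stop(length(missing_v), " variants lack an LD block assignment")
  }
  out <- marginal
  beta <- stats::setNames(marginal$effect_weight, marginal$variant_id)
  for (R in ld_blocks) {
    ids <- intersect(colnames(R), marginal$variant_id)
    if (!length(ids)) next
    Rb <- R[ids, ids, drop = FALSE]
    if (max(abs(Rb - t(Rb))) > 1e-8) stop("LD block matrix not symmetric")
    if (kappa == 0 && qr(Rb)$rank < ncol(Rb)) {
      stop("singular LD block with kappa = 0")
    }
    b <- solve(Rb + diag(kappa, ncol(Rb)), beta[ids])
    out$effect_weight[match(ids, out$variant_id)] <- b
  }
  attr(out, "provenance") <- "sblup"
  out
}

#' Compute polygenic scores
#'
#' `score_i = sum_v w_v d_iv`, where `d_iv` counts the weight file's effect
#' allele. Variants are matched by id and then by allele: an exact
#' effect/other match keeps the dosage, a swapped match flips it
#' (`d -> 2 - d`), strand-ambiguous pairs (A/T, C/G) are excluded, and any
#' other allele combination is dropped as a mismatch. Missing dosages are
#' replaced by `2 * frequency` (the per-variant mean under HWE). Exclusion
#' counts are reported via `message()` and attached as
#' `attr(, "match_counts")`.
#'
#' @param gm A [genotype_matrix()].
#' @param weights Weights data frame (see [read_weights()]).
#' @return Named numeric vector of scores, one per sample.
#' @export
compute_pgs <- function(gm, weights) {
  amb <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  idx <- match(weights$variant_id, gm$variants$variant_id)
  counts <- c(unmatched_id = sum(is.na(idx)), ambiguous = 0L,
              allele_mismatch = 0L, flipped = 0L, used = 0L)
  keep_w <- which(!is.na(idx))
  contrib <- matrix(0, nrow = length(gm$sample_ids), ncol = 0)
  score <- stats::setNames(numeric(length(gm$sample_ids)), gm$sample_ids)
  used_any <- FALSE
  for (k in keep_w) {
    j <- idx[k]
    ea <- gm$variants$effect_allele[j]; oa <- gm$variants$other_allele[j]
    we <- weights$effect_allele[k]; wo <- weights$other_allele[k]
    if (is.na(ea) || is.na(oa)) {
      d <- gm$dosages[, j]  # no allele metadata: match on id alone
    } else if (amb(ea, oa)) {
      counts["ambiguous"] <- counts["ambiguous"] + 1L
      next
    } else if (we == ea && wo == oa) {
      d <- gm$dosages[, j]
    } else if (we == oa && wo == ea) {
      d <- 2 - gm$dosages[, j]
      counts["flipped"] <- counts["flipped"] + 1L
    } else {
      counts["allele_mismatch"] <- counts["allele_mismatch"] + 1L
      next
    }
    miss <- is.na(d)
    if (any(miss)) {
      f <- gm$variants$frequency[j]
      if (is.na(ea) || we == ea) d[miss] <- 2 * f else d[miss] <- 2 * (1 - f)
    }
    score <- score + weights$effect_weight[k] * d
    counts["used"] <- counts["used"] + 1L
    used_any <- TRUE
  }
  if (!used_any) {
    stop("no variants usable for scoring; exclusions: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  dropped <- sum(counts[c("unmatched_id", "ambiguous", "allele_mismatch")])
  if (dropped > 0) {
    message("compute_pgs: ", counts["used"], " variants scored, ", dropped,
            " excluded (", counts["unmatched_id"], " unmatched, ",
            counts["ambiguous"], " strand-ambiguous, ",
            counts["allele_mismatch"], " allele mismatch)")
  }
  attr(score, "match_counts") <- counts
  score
}

#' Impute missing MZ co-twin scores
#'
#' A monozygotic twin without a score receives the co-twin's score (MZ twins
#' are genetically identical, so their true scores coincide). DZ twins are
#' never imputed. Pairs with both scores missing, or with missing zygosity,
#' are left unchanged with a warning.
#'
#' @param scores Named numeric vector of scores (names = sample ids); missing
#'   individuals may be absent or `NA`.
#' @param pedigree Data frame with `twin1_id`, `twin2_id`, `zygosity`.
#' @return Scores vector with MZ imputations applied; the number imputed is
#'   attached as `attr(, "n_imputed")`.
#' @export
impute_mz_pgs <- function(scores, pedigree) {
  n_imputed <- 0L
  get <- function(id) if (id %in% names(scores)) scores[[id]] else NA_real_
  for (i in seq_len(nrow(pedigree))) {
    z <- pedigree$zygosity[i]
    if (is.na(z)) {
      warning("missing zygosity for family ", pedigree$family_id[i],
              "; pair skipped")
      next
    }
    if (z != "MZ") next
    id1 <- pedigree$twin1_id[i]; id2 <- pedigree$twin2_id[i]
    s1 <- get(id1); s2 <- get(id2)
    if (is.na(s1) && is.na(s2)) {
      warning("both MZ co-twins unscored in family ", pedigree$family_id[i])
      next
    }
    if (is.na(s1)) { scores[id1] <- s2; n_imputed <- n_imputed + 1L }
    if (is.na(s2)) { scores[id2] <- s1; n_imputed <- n_imputed + 1L }
  }
  attr(scores, "n_imputed") <- n_imputed
  scores
}

#' Standardize table columns
#'
#' Transforms every non-exempt numeric column to mean 0, SD 1 (sample SD,
#' denominator `n - 1`). Exempt columns — typically sex, age and the
#' principal components — are returned byte-identical. Idempotent.
#'
#' @param table Data frame.
#' @param exempt_columns Character vector of column names to leave untouched.
#' @return Data frame with standardized columns.
#' @export
standardize_columns <- function(table, exempt_columns = character()) {
  for (nm in setdiff(names(table), exempt_columns)) {
    x <- table[[nm]]
    if (!is.numeric(x)) next
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero-variance column: ", nm)
    table[[nm]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}
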