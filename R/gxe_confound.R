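#' Pearson correlation with a Fisher-transform confidence interval
#'
#' `r = cor(x, y)`; the CI is `tanh(atanh(r) +/- z * 1/sqrt(n - 3))` and the
#' two-sided p-value comes from the same normal approximation. For paired
#' (twin) data pass one co-twin per vector and `n` is the number of pairs.
#'
#' @param x,y Numeric vectors of equal length (pairs of observations, at
#'   least 4 complete).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `correlation_result`: `r`, `n`, `ci_low`,
#'   `ci_high`, `p`, `contains_half` (NA unless set by
#'   [dz_pgs_correlation()]).
#' @export
pearson_r_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs of observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in an input vector")
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  sez <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(r = r, n = n,
                 ci_low = tanh(z - q * sez), ci_high = tanh(z + q * sez),
                 p = 2 * stats::pnorm(-abs(z) / sez),
                 contains_half = NA),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, p = %.3g, 95%% CI %.3f-%.3f)\n",
              x$r, x$n, x$p, x$ci_low, x$ci_high))
  if (!is.na(x$contains_half)) {
    cat("  CI", if (x$contains_half) "includes" else "excludes",
        "the expected DZ value 0.50\n")
  }
  invisible(x)
}

#' DZ co-twin polygenic-score correlation
#'
#' Pearson correlation of the two co-twins' scores across complete DZ pairs,
#' with a deterministic twin ordering (the lexicographically smaller sample
#' id is twin 1, so the result does not depend on pedigree row order). Under
#' random mating and no stratification the expectation is 0.50; an excess
#' suggests confounding such as assortative mating or population structure.
#' `contains_half` applies the inclusion rule at two-decimal precision, so a
#' bound that rounds to 0.50 counts as including it.
#'
#' @param scores Named numeric score vector.
#' @param pedigree Pedigree data frame (see [decompose_pgs()]).
#' @return A `correlation_result` with `contains_half` set.
#' @export
dz_pgs_correlation <- function(scores, pedigree) {
  dz <- pedigree[!is.na(pedigree$zygosity) & pedigree$zygosity == "DZ", ,
                 drop = FALSE]
  a <- pmin(dz$twin1_id, dz$twin2_id)
  b <- pmax(dz$twin1_id, dz$twin2_id)
  s1 <- scores[a]; s2 <- scores[b]
  res <- pearson_r_ci(s1, s2)
  res$contains_half <- round(res$ci_low, 2) <= 0.50 &&
    0.50 <= round(res$ci_high, 2)
  res
}

#' Verdict on the expected 0.50 DZ correlation
#'
#' Positions the Fisher CI of a DZ co-twin score correlation against the
#' Mendelian expectation of 0.50 (bounds compared at two decimals, boundary
#' inclusive).
#'
#' @param result A `correlation_result` from [dz_pgs_correlation()].
#' @return One of `"consistent with 0.50"`, `"exceeds 0.50"`,
#'   `"below 0.50"`.
#' @export
test_expected_half <- function(result) {
  stopifnot(inherits(result, "correlation_result"))
  lo <- round(result$ci_low, 2); hi <- round(result$ci_high, 2)
  if (lo <= 0.50 && 0.50 <= hi) return("consistent with 0.50")
  if (lo > 0.50) return("exceeds 0.50")
  "below 0.50"
}

#' Family musical-enrichment index
#'
#' First principal component of the standardized family-environment items
#' (records in the home, players in the environment, concert frequency,
#' early music education), computed from their correlation matrix. The sign
#' is oriented so the music-education item loads positively, i.e. higher
#' index = more enriched home. Constant items are dropped with a warning.
#'
#' @param items Data frame with a `family_id` column and the item columns.
#' @param orient_item Item whose loading fixes the sign (default
#'   `"music_edu_before12"`; falls back to the largest-magnitude loading if
#'   absent).
#' @return Data frame `family_id`, `enrichment_index`; loadings and the
#'   leading eigenvalue are attached as attributes.
#' @export
environment_index <- function(items, orient_item = "music_edu_before12") {
  stopifnot("family_id" %in% names(items))
  if (nrow(items) < 2) stop("need at least 2 families")
  Z <- items[, setdiff(names(items), "family_id"), drop = FALSE]
  Z <- Z[, vapply(Z, is.numeric, logical(1)), drop = FALSE]
  if (ncol(Z) < 2) stop("need at least 2 numeric item columns")
  sds <- vapply(Z, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("constant item column(s) dropped: ",
            paste(names(Z)[sds == 0], collapse = ", "))
    Z <- Z[, sds > 0, drop = FALSE]
  }
  Zs <- scale(as.matrix(Z))
  eg <- eigen(stats::cor(as.matrix(Z)), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  names(v1) <- colnames(Z)
  flip_by <- if (orient_item %in% names(v1)) {
    v1[orient_item]
  } else {
    v1[which.max(abs(v1))]
  }
  if (flip_by < 0) v1 <- -v1
  out <- data.frame(family_id = items$family_id,
                    enrichment_index = as.numeric(Zs %*% v1),
                    stringsAsFactors = FALSE)
  attr(out, "loadings") <- v1
  attr(out, "eigenvalue") <- eg$values[1]
  out
}

#' Expected squared prediction accuracy of a polygenic score
#'
#' The standard large-sample approximation
#' `r^2 = h2_snp / (1 + (M / N) * h2_snp)`: as the discovery GWAS grows
#' (`N -> Inf` for fixed `M`), the accuracy approaches the SNP heritability,
#' which bounds it from above.
#'
#' @param meta A [gwas_meta()].
#' @return Scalar expected r-squared.
#' @export
expected_r2 <- function(meta) {
  stopifnot(inherits(meta, "gwas_meta"))
  if (meta$N == 0) stop("N must be positive")
  meta$h2_snp / (1 + (meta$M / meta$N) * meta$h2_snp)
}
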