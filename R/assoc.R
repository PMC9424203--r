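#' Least-squares fit with R-squared
#'
#' Thin wrapper around [stats::lm.fit()] keeping what the association
#' pipeline needs: coefficients, fitted values, residuals and
#' `R^2 = 1 - RSS/TSS`. The design must include its own intercept column and
#' be of full column rank; collinear columns are named in the error.
#'
#' @param y Response vector, no missing values.
#' @param X Design matrix with intercept; columns should be named.
#' @return List of class `fampgs_lm` with `coefficients`, `fitted`,
#'   `residuals`, `r2`, `X`, `y`, `n`, `k`.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (anyNA(y) || anyNA(X)) stop("missing values must be dropped upstream")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = fit$coefficients,
                 fitted = as.numeric(fit$fitted.values),
                 residuals = as.numeric(fit$residuals),
                 r2 = 1 - rss / tss,
                 X = X, y = y, n = length(y), k = ncol(X)),
            class = "fampgs_lm")
}

#' Cluster-robust standard errors
#'
#' Sandwich covariance for clustered observations,
#' `(X'X)^-1 (sum_g X_g' e_g e_g' X_g) (X'X)^-1`, with the conventional
#' small-sample factor `G/(G-1) * (n-1)/(n-k)` (the Stata `vce(cluster)`
#' convention; when every observation is its own cluster it reduces to HC1
#' heteroskedasticity-robust SEs). Computed via [sandwich::vcovCL()].
#' P-values use a t distribution with `G - 1` degrees of freedom.
#'
#' @param fit A `fampgs_lm` from [fit_linear()].
#' @param cluster_ids Cluster membership, one per observation.
#' @return List with `vcov`, `se`, `t`, `p`, `df` (= G - 1), `n_clusters`.
#' @export
cluster_robust_se <- function(fit, cluster_ids) {
  if (length(cluster_ids) != fit$n) {
    stop("one cluster id per observation required")
  }
  G <- length(unique(cluster_ids))
  if (G < 2) stop("need at least 2 clusters")
  # refit as a genuine lm (X already carries the intercept) so sandwich's
  # estfun/bread machinery applies; point estimates are identical
  lmfit <- stats::lm(y ~ 0 + X, data = list(y = fit$y, X = fit$X))
  V <- sandwich::vcovCL(lmfit, cluster = cluster_ids, type = "HC1",
                        cadjust = TRUE)
  dimnames(V) <- list(colnames(fit$X), colnames(fit$X))
  se <- sqrt(diag(V))
  tval <- fit$coefficients / se
  list(vcov = V, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df = G - 1),
       df = G - 1, n_clusters = G)
}

#' Incremental R-squared of nested fits
#'
#' `R^2(full) - R^2(reduced)`; for nested least-squares fits on the same rows
#' this is non-negative and equals the variance uniquely explained by the
#' added predictor(s).
#'
#' @param full_fit,reduced_fit `fampgs_lm` objects on identical rows;
#'   `reduced_fit`'s design must be a subset of `full_fit`'s columns.
#' @return Scalar R-squared increment.
#' @export
delta_r2 <- function(full_fit, reduced_fit) {
  if (full_fit$n != reduced_fit$n ||
      max(abs(full_fit$y - reduced_fit$y)) > 0) {
    stop("full and reduced fits must use identical rows")
  }
  full_fit$r2 - reduced_fit$r2
}

#' Covariate-adjusted polygenic-score association
#'
#' The study's primary regression: outcome on PGS plus covariates (sex, age
#' and ancestry PCs in the canonical analysis), with cluster-robust inference
#' over families and the PGS effect size expressed as the R-squared increment
#' of adding the PGS to the covariate-only model. Rows with missing values in
#' any used column are dropped with a message. The phenotype and PGS are
#' expected to be standardized beforehand (see [standardize_columns()]), so
#' `beta` is in SD units.
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the outcome column.
#' @param pgs Name of the PGS column.
#' @param covariates Character vector of covariate column names; factors and
#'   character columns are expanded to dummies.
#' @param cluster Name of the cluster (family) id column.
#' @return Object of class `pgs_assoc` with fields `beta`, `se`, `p`,
#'   `delta_r2`, `n`, `n_clusters`, `covariates`, `outcome`, plus the full
#'   coefficient table and underlying fits.
#' @export
pgs_association <- function(data, outcome, pgs = "pgs",
                            covariates = c("sex", "age", paste0("PC", 1:10)),
                            cluster = "family_id") {
  used <- c(outcome, pgs, covariates, cluster)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  if (any(!cc)) {
    message("pgs_association: ", sum(!cc), " rows dropped for missingness")
  }
  d <- data[cc, , drop = FALSE]
  fml <- stats::as.formula(paste("~", paste(c(pgs, covariates), collapse = "+")))
  X <- stats::model.matrix(fml, d)
  y <- d[[outcome]]
  full <- fit_linear(y, X)
  reduced <- fit_linear(y, X[, colnames(X) != pgs, drop = FALSE])
  rob <- cluster_robust_se(full, d[[cluster]])
  j <- match(pgs, colnames(X))
  coefs <- data.frame(term = colnames(X), estimate = full$coefficients,
                      se = rob$se, t = rob$t, p = rob$p,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(beta = unname(full$coefficients[j]), se = unname(rob$se[j]),
                 p = unname(rob$p[j]),
                 delta_r2 = delta_r2(full, reduced),
                 r2_full = full$r2,
                 n = full$n, n_clusters = rob$n_clusters,
                 covariates = covariates, outcome = outcome, pgs = pgs,
                 coefficients = coefs, vcov = rob$vcov,
                 fit = full, reduced_fit = reduced),
            class = "pgs_assoc")
}

#' @export
print.pgs_assoc <- function(x, ...) {
  cat("PGS association:", x$outcome, "~", x$pgs, "+",
      paste(x$covariates, collapse = " + "), "\n")
  cat(sprintf("  beta = %.3f (cluster-robust SE %.3f, p = %.3g)\n",
              x$beta, x$se, x$p))
  cat(sprintf("  delta R2 = %.4f;  n = %d in %d families\n",
              x$delta_r2, x$n, x$n_clusters))
  invisible(x)
}

#' @export
summary.pgs_assoc <- function(object, ...) {
  print(object)
  cat("\nCoefficients (cluster-robust):\n")
  print(object$coefficients, digits = 3, row.names = FALSE)
  invisible(object$coefficients)
}

#' @export
coef.pgs_assoc <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.pgs_assoc <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$n_clusters - 1)
  est <- object$coefficients$estimate
  se <- object$coefficients$se
  out <- cbind(est - q * se, est + q * se)
  dimnames(out) <- list(object$coefficients$term,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.pgs_assoc <- function(object, ...) object$fit$residuals
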