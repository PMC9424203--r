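#' Split polygenic scores into family-mean and deviation components
#'
#' For each complete DZ twin pair, the between component is the family mean
#' score and the within component is the individual's deviation from it, so
#' `within + between = PGS` exactly and within components sum to zero in each
#' family. MZ pairs carry no within-pair genetic variation and are excluded;
#' incomplete pairs are dropped with a message.
#'
#' @param scores Named numeric vector of PGS values (names = sample ids).
#' @param pedigree Data frame with `family_id`, `twin1_id`, `twin2_id`,
#'   `zygosity`.
#' @return Data frame (two rows per retained pair): `sample_id`, `family_id`,
#'   `pgs`, `pgs_between`, `pgs_within`.
#' @export
decompose_pgs <- function(scores, pedigree) {
  dz <- pedigree[!is.na(pedigree$zygosity) & pedigree$zygosity == "DZ", ,
                 drop = FALSE]
  s1 <- scores[dz$twin1_id]; s2 <- scores[dz$twin2_id]
  complete <- !is.na(s1) & !is.na(s2)
  n_dropped <- sum(!complete) + (nrow(pedigree) - nrow(dz))
  if (n_dropped > 0) {
    message("decompose_pgs: ", sum(complete), " complete DZ pairs retained; ",
            sum(!complete), " incomplete DZ pairs and ",
            nrow(pedigree) - nrow(dz), " non-DZ families dropped")
  }
  dz <- dz[complete, , drop = FALSE]
  s1 <- s1[complete]; s2 <- s2[complete]
  if (!nrow(dz)) stop("no complete DZ pairs")
  fam_mean <- (s1 + s2) / 2
  data.frame(
    sample_id = c(rbind(dz$twin1_id, dz$twin2_id)),
    family_id = rep(dz$family_id, each = 2),
    pgs = c(rbind(s1, s2)),
    pgs_between = rep(fam_mean, each = 2),
    pgs_within = c(rbind(s1 - fam_mean, s2 - fam_mean)),
    row.names = NULL, stringsAsFactors = FALSE)
}

## -2 * restricted log-likelihood (up to an additive constant) profiled over
## the residual variance, as a function of theta = var_family / var_resid.
## Exploits the paired structure: V0^-1 per pair = I - c*J with
## c = theta / (1 + 2*theta), and log|V0| = n_pairs * log(1 + 2*theta).
reml_objective <- function(theta, y, X, fam) {
  cth <- theta / (1 + 2 * theta)
  S <- rowsum(X, fam)                 # pair-wise column sums of X
  sy <- rowsum(y, fam)
  A <- crossprod(X) - cth * crossprod(S)
  bvec <- crossprod(X, y) - cth * crossprod(S, sy)
  beta <- solve(A, bvec)
  r <- y - X %*% beta
  quad <- sum(r^2) - cth * sum(rowsum(as.numeric(r), fam)^2)
  n <- length(y); p <- ncol(X)
  n_fam <- nrow(S)
  obj <- n_fam * log(1 + 2 * theta) + (n - p) * log(quad) +
    determinant(A, logarithm = TRUE)$modulus
  list(objective = as.numeric(obj), beta = beta, A = A, quad = quad)
}

#' Random-intercept decomposition of the PGS effect
#'
#' Fits `Y_ij = a0 + bW (PGS_ij - mean PGS_j) + bB mean PGS_j + covariates +
#' g_j + e_ij` on complete DZ twin pairs, where `g_j` is a family random
#' intercept. Including the family-mean and deviation regressors together
#' makes the two fixed effects mutually adjusted: equal coefficients indicate
#' direct genetic effects, while an excess between-family coefficient points
#' to indirect (genetic-nurture) or confounding pathways. Variance components
#' are estimated by REML, profiling the criterion down to the single variance
#' ratio `var_family / var_resid` and optimizing it in one dimension; fixed
#' effects come from GLS at the optimum and their SEs from the GLS
#' covariance. 95% CIs are normal-approximation `estimate +/- 1.96 SE`.
#' A boundary estimate `var_family = 0` is allowed and reported.
#'
#' Age is deliberately not a covariate: co-twins share age exactly, so it is
#' collinear with the family intercept; the canonical covariate set is sex
#' plus ancestry PCs.
#'
#' @param data Data frame containing the outcome, the decomposed PGS columns
#'   (see [decompose_pgs()]), the covariates and the family id. Two rows per
#'   family (complete pairs).
#' @param outcome Outcome column name.
#' @param within,between Column names of the PGS deviation and family-mean
#'   components.
#' @param covariates Covariate column names (default sex + 10 PCs when
#'   present; missing PC columns are silently dropped from the default only).
#' @param family Family id column name.
#' @return Object of class `family_decomp` with `beta_within`,
#'   `beta_between`, `intercept`, `var_family`, `var_resid`, `se_within`,
#'   `se_between`, `ci95_within`, `ci95_between`, `n_pairs`, `converged`,
#'   `theta`, `reml` (criterion value), `coefficients`, `vcov`.
#' @export
fit_family_decomp <- function(data, outcome, within = "pgs_within",
                              between = "pgs_between",
                              covariates = NULL, family = "family_id") {
  if (is.null(covariates)) {
    covariates <- intersect(c("sex", paste0("PC", 1:10)), names(data))
  }
  used <- c(outcome, within, between, covariates, family)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  tab <- table(d[[family]])
  keep_fam <- names(tab)[tab == 2]
  dropped <- sum(tab != 2)
  if (dropped > 0) {
    message("fit_family_decomp: ", dropped,
            " families without a complete pair dropped")
  }
  d <- d[d[[family]] %in% keep_fam, , drop = FALSE]
  d <- d[order(d[[family]]), , drop = FALSE]
  n_pairs <- length(keep_fam)
  if (n_pairs < 3) stop("need at least 3 complete pairs, have ", n_pairs)
  if (n_pairs < 10) {
    warning("only ", n_pairs,
            " complete pairs; variance components will be unstable")
  }

  rhs <- paste(c(within, between, covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")
  y <- d[[outcome]]
  fam <- factor(d[[family]])

  opt <- stats::optimize(function(th) reml_objective(th, y, X, fam)$objective,
                         interval = c(0, 200), tol = 1e-8)
  theta <- opt$minimum
  # the optimum may sit at the var_family = 0 boundary
  at0 <- reml_objective(0, y, X, fam)
  converged <- TRUE
  if (at0$objective <= opt$objective + 1e-10) {
    theta <- 0
  } else if (theta > 199) {
    converged <- FALSE  # ran into the search bound
  }
  sol <- reml_objective(theta, y, X, fam)
  n <- length(y); p <- ncol(X)
  var_resid <- sol$quad / (n - p)
  var_family <- theta * var_resid
  vc <- var_resid * solve(sol$A)
  dimnames(vc) <- list(colnames(X), colnames(X))
  est <- stats::setNames(as.numeric(sol$beta), colnames(X))
  se <- sqrt(diag(vc))
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                      z = zval, p = pval,
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(beta_within = est[[within]], beta_between = est[[between]],
                 intercept = est[["(Intercept)"]],
                 var_family = var_family, var_resid = var_resid,
                 se_within = se[[within]], se_between = se[[between]],
                 ci95_within = ci[match(within, colnames(X)), ],
                 ci95_between = ci[match(between, colnames(X)), ],
                 n_pairs = n_pairs, converged = converged,
                 theta = theta, reml = sol$objective,
                 coefficients = coefs, vcov = vc,
                 within = within, between = between, outcome = outcome),
            class = "family_decomp")
}

#' @export
print.family_decomp <- function(x, ...) {
  cat("Within/between-family PGS decomposition (", x$n_pairs,
      " complete DZ pairs)\n", sep = "")
  tab <- data.frame(
    Effect = c("Between", "Within"),
    Beta = c(x$beta_between, x$beta_within),
    `Std. error` = c(x$se_between, x$se_within),
    `CI lower 95%` = c(x$ci95_between[1], x$ci95_within[1]),
    `CI upper 95%` = c(x$ci95_between[2], x$ci95_within[2]),
    check.names = FALSE)
  print(tab, digits = 3, row.names = FALSE)
  cat(sprintf("Variance components: family %.4f, residual %.4f%s\n",
              x$var_family, x$var_resid,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @export
summary.family_decomp <- function(object, ...) {
  print(object)
  cat("\nAll fixed effects:\n")
  print(object$coefficients, digits = 3, row.names = FALSE)
  cmp <- compare_within_between(object)
  cat(sprintf("\nBetween - within: %.3f (z = %.2f, p = %.3f); 95%% CIs %s\n",
              cmp$difference, cmp$z, cmp$p,
              if (cmp$ci_overlap) "overlap" else "do not overlap"))
  invisible(object)
}

#' @export
coef.family_decomp <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.family_decomp <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients$estimate
  se <- object$coefficients$se
  out <- cbind(est - q * se, est + q * se)
  dimnames(out) <- list(object$coefficients$term,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Compare the between- and within-family effects
#'
#' Reports `beta_between - beta_within` with a Wald z-test using the joint
#' GLS covariance of the two fixed effects, and also the cruder
#' confidence-interval-overlap indicator (overlapping 95% CIs read as "no
#' significant difference").
#'
#' @param result A converged `family_decomp` object.
#' @return List with `difference`, `z`, `p`, `ci_overlap`.
#' @export
compare_within_between <- function(result) {
  stopifnot(inherits(result, "family_decomp"))
  vb <- result$vcov[result$between, result$between]
  vw <- result$vcov[result$within, result$within]
  cv <- result$vcov[result$between, result$within]
  diff <- result$beta_between - result$beta_within
  se_diff <- sqrt(vb + vw - 2 * cv)
  z <- if (se_diff > 0) diff / se_diff else 0
  p <- if (se_diff > 0) 2 * stats::pnorm(-abs(z)) else 1
  overlap <- result$ci95_between[1] <= result$ci95_within[2] &&
    result$ci95_within[1] <= result$ci95_between[2]
  list(difference = unname(diff), z = unname(z), p = unname(p),
       ci_overlap = unname(overlap))
}
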