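test_that("PGS decomposition is an exact arithmetic identity", {
  ped <- toy_pedigree(3)
  s <- c(F001_T1 = 1, F001_T2 = 1,
         F002_T1 = 1, F002_T2 = -1,
         F003_T1 = 0.4, F003_T2 = 1.2)
  dec <- decompose_pgs(s, ped)
  expect_equal(dec$pgs_within + dec$pgs_between, dec$pgs, tolerance = 1e-12)
  expect_equal(dec$pgs_within[1:2], c(0, 0))        # equal co-twin scores
  expect_equal(dec$pgs_between[3:4], c(0, 0))       # symmetric pair (1, -1)
  expect_equal(dec$pgs_within[3:4], c(1, -1))
  # within components cancel inside every family
  expect_equal(as.numeric(tapply(dec$pgs_within, dec$family_id, sum)),
               rep(0, 3), tolerance = 1e-12)
})

test_that("MZ and incomplete pairs are excluded from the decomposition", {
  ped <- toy_pedigree(3, zygosity = c("DZ", "MZ", "DZ"))
  s <- c(F001_T1 = 1, F001_T2 = 0, F002_T1 = 1, F002_T2 = 1, F003_T1 = 2)
  expect_message(dec <- decompose_pgs(s, ped), "1 complete DZ pairs")
  expect_identical(unique(dec$family_id), "F001")
  expect_error(suppressMessages(
    decompose_pgs(c(F001_T1 = 1), toy_pedigree(1))), "no complete DZ pairs")
})

test_that("balanced pairs make within and between regressors orthogonal", {
  set.seed(50)
  d <- toy_pair_data(200, bw = 0.2, bb = 0.2)
  expect_lt(abs(sum(d$pgs_within * (d$pgs_between - mean(d$pgs_between)))),
            1e-10)
})

test_that("zero family variance reduces the REML fit to OLS", {
  d <- toy_pair_data(150, bw = 0.3, bb = 0.3, sd_fam = 0, sd_e = 1, seed = 51)
  fit <- fit_family_decomp(d, "y", covariates = "sex_num")
  ols <- lm(y ~ pgs_within + pgs_between + sex_num, data = d)
  expect_lt(max(abs(coef(fit)[names(coef(ols))] - coef(ols))), 1e-6)
})

test_that("the REML optimum beats a dense grid search on a small toy", {
  d <- toy_pair_data(12, bw = 0.4, bb = 0.1, sd_fam = 0.5, sd_e = 0.8,
                     seed = 52)
  fit <- fit_family_decomp(d, "y", covariates = "sex_num")

  # dense oracle: explicit V0 = I + theta ZZ', generic matrix algebra
  X <- cbind(1, d$pgs_within, d$pgs_between, as.integer(d$sex_num))
  y <- d$y
  fam <- factor(d$family_id)
  Z <- stats::model.matrix(~ 0 + fam)
  dense_obj <- function(theta) {
    V0 <- diag(nrow(X)) + theta * tcrossprod(Z)
    Vi <- solve(V0)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    quad <- drop(t(r) %*% Vi %*% r)
    as.numeric(determinant(V0, TRUE)$modulus) +
      (nrow(X) - ncol(X)) * log(quad) +
      as.numeric(determinant(A, TRUE)$modulus)
  }
  grid <- seq(0, 5, by = 0.001)
  grid_min <- min(vapply(grid, dense_obj, numeric(1)))
  expect_lt(fit$reml, grid_min + 1e-6)
  # and the criterion agrees with the dense formula at the optimum
  expect_equal(fit$reml, dense_obj(fit$theta), tolerance = 1e-8)
})

test_that("fixed effects, SEs and variance components match lme4", {
  skip_if_not_installed("lme4")
  d <- toy_pair_data(250, bw = 0.25, bb = 0.45, sd_fam = 0.4, sd_e = 0.8,
                     seed = 53)
  fit <- fit_family_decomp(d, "y", covariates = "sex_num")
  lf <- lme4::lmer(y ~ pgs_within + pgs_between + sex_num + (1 | family_id),
                   data = d, REML = TRUE)
  expect_equal(unname(coef(fit)[c("(Intercept)", "pgs_within", "pgs_between",
                                  "sex_num")]),
               unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients$se),
               unname(sqrt(diag(as.matrix(vcov(lf))))), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(c(fit$var_family, fit$var_resid), vc$vcov, tolerance = 1e-4)
})

test_that("CIs contain their estimates and variances are non-negative", {
  d <- toy_pair_data(80, bw = 0.3, bb = 0.1, seed = 54)
  fit <- fit_family_decomp(d, "y", covariates = "sex_num")
  expect_gte(fit$var_family, 0); expect_gt(fit$var_resid, 0)
  expect_true(fit$ci95_within[1] <= fit$beta_within &&
                fit$beta_within <= fit$ci95_within[2])
  expect_true(fit$ci95_between[1] <= fit$beta_between &&
                fit$beta_between <= fit$ci95_between[2])
  expect_true(fit$converged)
})

test_that("the Wald comparison reproduces a hand-computed z", {
  d <- toy_pair_data(50, bw = 0.2, bb = 0.2, seed = 55)
  fit <- fit_family_decomp(d, "y", covariates = "sex_num")

  # equal betas by construction of a doctored object -> difference 0, p = 1
  fake <- fit
  fake$beta_between <- fake$beta_within <- 0.2
  fake$vcov[fit$between, fit$between] <- 0.0016
  fake$vcov[fit$within, fit$within] <- 0.0049
  fake$vcov[fit$between, fit$within] <-
    fake$vcov[fit$within, fit$between] <- 0
  cmp0 <- compare_within_between(fake)
  expect_equal(cmp0$difference, 0)
  expect_equal(cmp0$p, 1)
  expect_true(cmp0$ci_overlap)

  # between 0.04 (SE 0.04) vs within 0.15 (SE 0.07), zero covariance:
  # |z| = 0.11 / sqrt(0.0016 + 0.0049) ~ 1.36, p ~ 0.17
  fake$beta_between <- 0.04; fake$beta_within <- 0.15
  cmp <- compare_within_between(fake)
  expect_equal(abs(cmp$z), 0.11 / sqrt(0.0065), tolerance = 1e-10)
  expect_equal(cmp$p, 0.172, tolerance = 0.005)
})

test_that("genetic nurture splits the between and within effects", {
  # eta > 0: between exceeds within in expectation; recovery of both
  cfg <- sim_config(n_families = 2500, n_snps = 150, delta = 0.3, eta = 0.3,
                    sigma_c = 0.2, gwas_noise_sd = 0, prop_mz = 0, seed = 56)
  sim <- simulate_twin_study(cfg)
  s <- compute_pgs(sim$genotypes, sim$weights)
  s <- s / sd(s)
  dec <- suppressMessages(decompose_pgs(s, sim$pedigree))
  dd <- merge(dec, sim$phenotypes[, c("sample_id", "sex", "phenotype")],
              by = "sample_id")
  dd$sex_num <- as.integer(dd$sex == "M")
  fit <- fit_family_decomp(dd, "phenotype", covariates = "sex_num")
  expect_gt(fit$beta_between, fit$beta_within)
  # within effect estimates the direct coefficient delta
  expect_lt(abs(fit$beta_within - 0.3), 2.5 * fit$se_within + 0.02)
})
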