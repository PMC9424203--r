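test_that("weight tables round-trip through TSV", {
  w <- toy_weights(3, w = c(0.1, -0.2, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$effect_weight, w$effect_weight)
  expect_identical(attr(back, "provenance"), "marginal")

  w_bad <- w; w_bad$variant_id[2] <- w_bad$variant_id[1]
  write_weights(w_bad, path)
  expect_error(read_weights(path), "duplicated")
})

test_that("SBLUP solves (R + kappa I) b = beta per block", {
  # identity LD, tiny kappa: weights barely shrink, ratio 1/(1+kappa)
  w <- toy_weights(4, w = c(0.1, -0.3, 0.2, 0.05))
  R <- diag(4); dimnames(R) <- list(w$variant_id, w$variant_id)
  meta <- gwas_meta(h2_snp = 0.5, M = 4, N = 4e6)  # kappa = 1e-6
  b <- sblup_reweight(w, list(R), meta)
  expect_equal(b$effect_weight, w$effect_weight / (1 + 1e-6), tolerance = 1e-12)
  expect_identical(attr(b, "provenance"), "sblup")

  # hand-solved 2x2: r = 1, beta = (0.1, 0.1), kappa = 1 -> b = (1/30, 1/30)
  w2 <- toy_weights(2, w = c(0.1, 0.1))
  R2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(w2$variant_id, w2$variant_id))
  meta2 <- gwas_meta(h2_snp = 0.5, M = 10, N = 10)  # kappa = M(1/h2-1)/N = 1
  b2 <- sblup_reweight(w2, list(R2), meta2)
  expect_equal(b2$effect_weight, c(1 / 30, 1 / 30), tolerance = 1e-12)

  # shrinkage property under identity LD
  metaS <- gwas_meta(0.3, 50, 100)
  RS <- diag(4); dimnames(RS) <- list(w$variant_id, w$variant_id)
  bS <- sblup_reweight(w, list(RS), metaS)
  expect_lt(sqrt(sum(bS$effect_weight^2)), sqrt(sum(w$effect_weight^2)))

  # every variant needs a block
  expect_error(sblup_reweight(w, list(R[1:2, 1:2]), meta), "LD block")
})

test_that("SBLUP weights agree with individual-level ridge regression", {
  set.seed(30)
  n <- 3000; m <- 24
  # blocky LD via shared latent factors
  blk <- rep(1:3, each = 8)
  X <- sapply(1:m, function(j) {
    rnorm(n)
  })
  for (b in 1:3) {
    f <- rnorm(n)
    X[, blk == b] <- 0.75 * f + 0.66 * X[, blk == b]
  }
  X <- scale(X)
  beta_true <- rnorm(m, 0, 0.05)
  y <- drop(X %*% beta_true + rnorm(n))
  h2 <- drop(var(X %*% beta_true)) / var(y)

  marg <- drop(crossprod(X, y)) / n            # marginal betas, standardized X
  ids <- sprintf("v%02d", 1:m)
  w <- data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
                  effect_weight = marg, stringsAsFactors = FALSE)
  meta <- gwas_meta(h2_snp = h2, M = m, N = n)
  ld <- lapply(1:3, function(b) {
    R <- cor(X[, blk == b]); dimnames(R) <- list(ids[blk == b], ids[blk == b])
    R
  })
  sb <- sblup_reweight(w, ld, meta)

  # oracle: explicit ridge with the matching penalty lambda = M (1/h2 - 1),
  # using the full X (SBLUP approximates its block-diagonal LD)
  lambda <- m * (1 / h2 - 1)
  ridge <- solve(crossprod(X) + diag(lambda, m), crossprod(X, y))
  expect_gt(cor(sb$effect_weight, drop(ridge)), 0.99)
})

test_that("PGS computation handles alleles, flips, and missingness", {
  gm <- toy_gm(c(0, 1, 2), c(2, 1, 0))
  w0 <- toy_weights(2, w = c(0, 0))
  expect_true(all(compute_pgs(gm, w0) == 0))

  w1 <- toy_weights(1, w = 1)
  expect_equal(unname(compute_pgs(toy_gm(c(0, 1, 2)), w1)), c(0, 1, 2),
               ignore_attr = TRUE)

  # recoding a variant (swap allele labels, d -> 2 - d) leaves centered
  # scores identical: the flip logic undoes the recoding
  gmA <- toy_gm(c(0, 1, 2, 2, 1))
  gmA_flip <- toy_gm(2 - c(0, 1, 2, 2, 1), effect = "G", other = "A")
  wA <- toy_weights(1, w = 0.4)
  sA <- compute_pgs(gmA, wA)
  sB <- suppressMessages(compute_pgs(gmA_flip, wA))
  expect_equal(sA - mean(sA), sB - mean(sB), tolerance = 1e-12,
               ignore_attr = TRUE)

  # linearity in weights
  g2 <- toy_gm(c(0, 1, 2), c(2, 0, 1))
  wX <- toy_weights(2, w = c(0.2, -0.1)); wY <- toy_weights(2, w = c(0.3, 0.5))
  wXY <- toy_weights(2, w = c(0.5, 0.4))
  expect_equal(compute_pgs(g2, wXY),
               compute_pgs(g2, wX) + compute_pgs(g2, wY), tolerance = 1e-12,
               ignore_attr = TRUE)

  # strand-ambiguous variants are excluded
  gAmb <- toy_gm(c(0, 1, 2), c(1, 1, 1), effect = c("A", "A"),
                 other = c("T", "G"))
  wAmb <- toy_weights(2, w = c(1, 1), effect = c("A", "A"),
                      other = c("T", "G"))
  expect_message(sAmb <- compute_pgs(gAmb, wAmb), "strand-ambiguous")
  expect_equal(unname(sAmb), c(1, 1, 1),  # only the unambiguous variant scores
               ignore_attr = TRUE)

  # missing dosage imputed at 2 * effect-allele frequency
  gMiss <- toy_gm(c(0, 2, NA, 2))  # freq from observed mean = 4/8... NA-aware
  f <- mean(c(0, 2, 2)) / 2
  sMiss <- compute_pgs(gMiss, toy_weights(1, w = 1))
  expect_equal(unname(sMiss[3]), 2 * f)

  # zero overlap errors with exclusion counts
  wNo <- toy_weights(1); wNo$variant_id <- "zzz"
  expect_error(compute_pgs(gmA, wNo), "no variants usable")
})

test_that("MZ co-twin imputation copies scores only where justified", {
  ped <- toy_pedigree(3, zygosity = c("MZ", "DZ", "MZ"))
  s <- c(F001_T1 = 1.2, F002_T1 = 0.5, F003_T1 = NA, F003_T2 = NA)
  out <- suppressWarnings(impute_mz_pgs(s, ped))
  expect_equal(unname(out["F001_T2"]), 1.2)      # MZ: imputed from co-twin
  expect_false("F002_T2" %in% names(out)[!is.na(out)])  # DZ: untouched
  expect_true(all(is.na(out[c("F003_T1", "F003_T2")])))
  expect_warning(impute_mz_pgs(s, ped), "both MZ co-twins unscored")
  expect_equal(attr(out, "n_imputed"), 1L)

  ped_na <- ped; ped_na$zygosity[1] <- NA
  ws <- testthat::capture_warnings(impute_mz_pgs(s, ped_na))
  expect_true(any(grepl("missing zygosity", ws)))
})

test_that("standardization is exact, exempting, and idempotent", {
  d <- data.frame(a = c(1, 2, 3), sex = c(0, 1, 0), b = c(10, 20, 60))
  out <- standardize_columns(d, exempt_columns = "sex")
  expect_equal(out$a, c(-1, 0, 1))
  expect_identical(out$sex, d$sex)
  expect_equal(standardize_columns(out, "sex"), out, tolerance = 1e-12)
  expect_error(standardize_columns(data.frame(k = rep(2, 5))), "k")
})
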