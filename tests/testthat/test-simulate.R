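test_that("Balding-Nichols frequencies have the analytic Beta moments", {
  # fst = 0 must return the ancestral frequencies exactly
  f0 <- draw_subpop_frequencies(c(0.3, 0.3, 0.3), fst = 0, n_subpops = 3)
  expect_identical(dim(f0), c(3L, 3L))
  expect_true(all(f0 == 0.3))

  set.seed(1)
  for (fst in c(0.1, 0.5)) {
    f <- draw_subpop_frequencies(rep(0.5, 1e5), fst = fst, n_subpops = 1)
    expect_equal(mean(f), 0.5, tolerance = 0.01)
    expect_equal(stats::var(as.numeric(f)), fst * 0.25, tolerance = 0.05)
  }

  expect_error(draw_subpop_frequencies(0.5, fst = 1, n_subpops = 2), "fst")
  expect_error(draw_subpop_frequencies(numeric(0), 0.1, 2), "empty")
})

test_that("parental genotypes are HWE binomial draws", {
  set.seed(2)
  g0 <- sample_parent_genotypes(rep(0, 5), n = 100)
  expect_true(all(g0$dosages == 0))

  g <- sample_parent_genotypes(0.5, n = 1e4)
  expect_equal(mean(g$dosages), 1, tolerance = 0.03)
  expect_equal(stats::var(g$dosages[, 1]), 0.5, tolerance = 0.05)

  # HWE genotype class frequencies at p = 0.3, chi-squared oracle
  g3 <- sample_parent_genotypes(0.3, n = 1e4)
  counts <- tabulate(g3$dosages[, 1] + 1, nbins = 3)
  chi <- stats::chisq.test(counts, p = c(0.49, 0.42, 0.09))
  expect_gt(chi$p.value, 0.01)

  expect_error(sample_parent_genotypes(0.5, n = 0), "positive")
})

test_that("LD blocks induce the requested adjacent-variant correlation", {
  set.seed(3)
  g <- sample_parent_genotypes(rep(0.5, 20), n = 4000, rho_ld = 0.7,
                               n_blocks = 2)
  h <- attr(g, "haplotypes")$h1
  adj <- vapply(1:19, function(j) cor(h[, j], h[, j + 1]), numeric(1))
  # allele-level correlation of a Gaussian-threshold copula at p = 0.5 is
  # below the latent rho; check positivity within blocks, absence across
  expect_true(all(adj[c(1:9, 11:19)] > 0.25))
  expect_lt(abs(adj[10]), 0.05)  # block boundary between variants 10 and 11
})

test_that("assortative mating attains the target spousal correlation", {
  set.seed(4)
  ym <- rnorm(5000); yf <- rnorm(5000)
  wife0 <- mate_assortatively(ym, yf, 0)
  expect_lt(abs(cor(ym, yf[wife0])), 0.05)

  wife1 <- mate_assortatively(ym, yf, 1)
  expect_equal(cor(ym, yf[wife1], method = "spearman"), 1)
  # perfect assortment is exact rank-sorted matching
  expect_identical(rank(ym), rank(yf[wife1]))

  wife4 <- mate_assortatively(ym, yf, 0.4)
  r <- cor(ym, yf[wife4])
  expect_gt(r, 0.35); expect_lt(r, 0.45)

  expect_error(mate_assortatively(ym, yf[-1], 0.4), "unequal")
})

test_that("meiosis is Mendelian and MZ pairs duplicate one meiosis", {
  set.seed(5)
  m <- meiosis(rep(2, 50), rep(0, 50), "DZ")
  expect_true(all(m$twin1 == 1) && all(m$twin2 == 1))

  m2 <- meiosis(matrix(1, 1e4, 1), matrix(1, 1e4, 1), "DZ")
  counts <- tabulate(m2$twin1 + 1, nbins = 3)
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.01)

  mz <- meiosis(matrix(rbinom(500, 2, 0.4), 5, 100),
                matrix(rbinom(500, 2, 0.4), 5, 100), "MZ")
  expect_identical(mz$twin1, mz$twin2)

  expect_error(meiosis(3, 0), "dosages")
})

test_that("IBD sharing among DZ twins is 50% with binomial spread", {
  set.seed(6)
  L <- 200
  m <- meiosis(matrix(1, 1000, L), matrix(1, 1000, L), "DZ")
  sh <- ibd_share(m$transmission)
  expect_equal(mean(sh), 0.5, tolerance = 0.01)
  # per-locus share variance is 0.125 ((1/4, 1/2, 1/4) over (0, 1/2, 1))
  expect_equal(sd(sh), sqrt(0.125 / L), tolerance = 0.1)

  mz <- meiosis(matrix(1, 50, 20), matrix(1, 50, 20), "MZ")
  expect_true(all(ibd_share(mz$transmission) == 1))
  expect_error(ibd_share(list(pat1 = integer(0))), "empty")
})

test_that("phenotype model recovers its generative coefficients by OLS", {
  cfg0 <- sim_config(delta = 0, eta = 0, sigma_c = 0)
  set.seed(7)
  y0 <- simulate_phenotype(rnorm(2e4), rnorm(2e4), rep(1L, 2e4),
                           rep(0, 2e4), cfg0)
  expect_equal(stats::var(y0), 1, tolerance = 0.03)

  cfg1 <- sim_config(delta = 0.7, eta = 0, sigma_c = 0)
  g <- rnorm(2e4)
  y1 <- simulate_phenotype(g, rnorm(2e4), rep(1L, 2e4), rep(0, 2e4), cfg1)
  expect_equal(unname(coef(lm(y1 ~ g))[2]), 0.7, tolerance = 0.02)

  cfg2 <- sim_config(delta = 0.5, eta = 0.3, sigma_c = 0)
  gm <- 0.5 * g + sqrt(0.75) * rnorm(2e4)
  y2 <- simulate_phenotype(g, gm, rep(1L, 2e4), rep(0, 2e4), cfg2)
  expect_equal(unname(coef(lm(y2 ~ g + gm))[2:3]), c(0.5, 0.3),
               tolerance = 0.03)

  # infeasible variance budget is rejected with the component report
  cfg_bad <- sim_config(delta = 0.9, eta = 0.6, sigma_c = 0.5)
  expect_error(simulate_phenotype(g, g, rep(1L, 2e4), rep(0, 2e4), cfg_bad),
               "variance budget")
})

test_that("environment items track the mid-parent genetic value", {
  set.seed(8)
  gm <- rnorm(5000)
  e0 <- simulate_environment_items(gm, enrichment_loading = 0)
  expect_lt(abs(cor(attr(e0, "latent"), gm)), 0.03)

  e5 <- simulate_environment_items(gm, enrichment_loading = 0.5)
  r <- cor(attr(e5, "latent"), gm)
  expect_gt(r, 0.45); expect_lt(r, 0.55)

  expect_true(all(e5$n_records >= 0) && all(e5$n_players >= 0))
  expect_true(all(e5$concert_freq %in% 0:4))
  expect_true(all(e5$music_edu_before12 %in% 0:1))
})

test_that("identical config and seed reproduce the study exactly", {
  cfg <- sim_config(n_families = 60, n_snps = 40, n_subpops = 2, fst = 0.05,
                    rho_mate = 0.3, eta = 0.2, seed = 99)
  s1 <- simulate_twin_study(cfg)
  s2 <- simulate_twin_study(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$environment_items, s2$environment_items)
})

test_that("MZ twins are genetically identical and ids are coherent", {
  cfg <- sim_config(n_families = 80, n_snps = 30, prop_mz = 1, seed = 12)
  sim <- simulate_twin_study(cfg)
  i1 <- match(sim$pedigree$twin1_id, sim$genotypes$sample_ids)
  i2 <- match(sim$pedigree$twin2_id, sim$genotypes$sample_ids)
  expect_identical(unname(sim$genotypes$dosages[i1, ]),
                   unname(sim$genotypes$dosages[i2, ]))
  ids <- c(sim$pedigree$father_id, sim$pedigree$mother_id,
           sim$pedigree$twin1_id, sim$pedigree$twin2_id)
  expect_false(anyDuplicated(ids) > 0)
})

test_that("assortative mating inflates the DZ correlation as (1+rho)/(2+rho)", {
  # single-generation result verified by brute force; rho is the realized
  # spousal correlation of the true genetic value
  cfg <- sim_config(n_families = 4000, n_snps = 200, rho_mate = 0.8,
                    prop_mz = 0, delta = 0.9, sigma_c = 0,
                    gwas_noise_sd = 0, seed = 13)
  sim <- simulate_twin_study(cfg)
  s <- compute_pgs(sim$genotypes, sim$weights)
  r <- suppressMessages(dz_pgs_correlation(s, sim$pedigree))$r
  rho <- sim$spousal_pgs_r
  expect_gt(rho, 0.3)  # mating must actually have bitten
  expect_equal(r, (1 + rho) / (2 + rho), tolerance = 0.04)
})
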