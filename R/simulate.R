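#' Configuration for the twin-family simulator
#'
#' Defines the generative model behind [simulate_twin_study()]: one twin pair
#' per family, parents drawn from one or more subpopulations whose allele
#' frequencies diverge under a Balding-Nichols model, phenotypic assortative
#' mating, Mendelian transmission to DZ twins (MZ twins duplicate one
#' meiosis), and a phenotype built from a direct genetic effect, a
#' genetic-nurture (passive gene-environment correlation) effect of the
#' mid-parent genetic value, a shared family environment, an additive
#' subpopulation shift and independent noise. The residual SD is chosen so
#' the total phenotypic variance is 1 when the stated components permit it.
#'
#' @param n_families Number of twin families.
#' @param n_snps Number of biallelic variants.
#' @param n_blocks Number of LD blocks (relevant when `rho_ld > 0`).
#' @param rho_ld Adjacent-variant haplotype correlation within a block, in
#'   `[0, 1)`; 0 gives unlinked variants.
#' @param n_subpops Number of subpopulations (>= 1).
#' @param fst Wright's F_ST governing subpopulation frequency divergence, in
#'   `[0, 1)`.
#' @param maf_range Range `(low, high)` of ancestral allele frequencies.
#' @param delta Direct effect of the child's standardized true genetic value
#'   on the phenotype.
#' @param eta Nurture effect of the standardized mid-parent genetic value.
#' @param sigma_c SD of the shared family environment component (>= 0).
#' @param stratum_effect Per-subpopulation phenotype shift: a vector of length
#'   `n_subpops`, or a single scale `s` expanded to centered, equally spaced
#'   shifts `s * (k - (K+1)/2)`.
#' @param rho_mate Target spousal phenotype correlation in `[-1, 1]`.
#' @param gwas_noise_sd SD of the estimation noise added to the true
#'   per-variant effects to emulate marginal GWAS weights.
#' @param h2_true Variance of the true genetic value on the standardized
#'   genotype scale; true per-variant effects are `N(0, h2_true / n_snps)`.
#' @param enrichment_loading Loading of the latent family musical-enrichment
#'   score on the standardized mid-parent genetic value, in `[0, 1]`.
#' @param prop_mz Proportion of MZ twin pairs in `[0, 1]`.
#' @param seed Integer RNG seed; identical config + seed reproduces identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 1000, n_snps = 500, n_blocks = 1,
                       rho_ld = 0, n_subpops = 1, fst = 0,
                       maf_range = c(0.1, 0.5), delta = 0.35, eta = 0,
                       sigma_c = 0.3, stratum_effect = 0, rho_mate = 0,
                       gwas_noise_sd = 0.02, h2_true = 0.5,
                       enrichment_loading = 0.5, prop_mz = 0.4, seed = 1L) {
  stopifnot(n_families >= 1, n_snps >= 1, n_blocks >= 1, n_subpops >= 1)
  if (rho_ld < 0 || rho_ld >= 1) stop("rho_ld must be in [0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be (low, high) within (0, 1)")
  }
  if (abs(rho_mate) > 1) stop("rho_mate must be in [-1, 1]")
  if (sigma_c < 0) stop("sigma_c must be >= 0")
  if (gwas_noise_sd < 0) stop("gwas_noise_sd must be >= 0")
  if (h2_true <= 0 || h2_true >= 1) stop("h2_true must be in (0, 1)")
  if (enrichment_loading < 0 || enrichment_loading > 1) {
    stop("enrichment_loading must be in [0, 1]")
  }
  if (prop_mz < 0 || prop_mz > 1) stop("prop_mz must be in [0, 1]")
  if (length(stratum_effect) == 1 && n_subpops > 1) {
    stratum_effect <- stratum_effect * (seq_len(n_subpops) - (n_subpops + 1) / 2)
  }
  if (length(stratum_effect) != n_subpops && n_subpops > 1) {
    stop("stratum_effect must have length 1 or n_subpops")
  }
  cfg <- list(n_families = as.integer(n_families), n_snps = as.integer(n_snps),
              n_blocks = as.integer(n_blocks), rho_ld = rho_ld,
              n_subpops = as.integer(n_subpops), fst = fst,
              maf_range = maf_range, delta = delta, eta = eta,
              sigma_c = sigma_c, stratum_effect = stratum_effect,
              rho_mate = rho_mate, gwas_noise_sd = gwas_noise_sd,
              h2_true = h2_true, enrichment_loading = enrichment_loading,
              prop_mz = prop_mz, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Subpopulation allele frequencies under the Balding-Nichols model
#'
#' Each subpopulation's frequency at a variant with ancestral frequency `p`
#' is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is `p` and whose
#' variance is `F p (1-p)`. With `fst = 0` the ancestral frequencies are
#' returned exactly. Draws are clipped to `(0.001, 0.999)` so downstream
#' binomial sampling never degenerates.
#'
#' @param ancestral_freqs Vector of ancestral frequencies in `(0, 1)`.
#' @param fst Wright's F_ST in `[0, 1)`.
#' @param n_subpops Number of subpopulations.
#' @return Matrix, `n_subpops` rows x variants columns.
#' @export
draw_subpop_frequencies <- function(ancestral_freqs, fst, n_subpops) {
  if (length(ancestral_freqs) == 0) stop("empty frequency vector")
  if (any(ancestral_freqs <= 0) || any(ancestral_freqs >= 1)) {
    stop("ancestral frequencies must be in (0, 1)")
  }
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  m <- length(ancestral_freqs)
  if (fst == 0) {
    return(matrix(ancestral_freqs, nrow = n_subpops, ncol = m, byrow = TRUE))
  }
  a <- ancestral_freqs * (1 - fst) / fst
  b <- (1 - ancestral_freqs) * (1 - fst) / fst
  f <- matrix(stats::rbeta(n_subpops * m, rep(a, each = n_subpops),
                           rep(b, each = n_subpops)),
              nrow = n_subpops, ncol = m)
  pmin(pmax(f, 0.001), 0.999)
}

## haplotypes for n individuals: 2 binary matrices (n x m). Under LD, adjacent
## variants within a block share a Gaussian AR(1) latent with correlation
## rho_ld (threshold copula), so allele-level LD decays geometrically.
sample_haplotypes <- function(freqs, n, rho_ld = 0, block_id = NULL) {
  m <- length(freqs)
  if (rho_ld == 0) {
    return(matrix(stats::rbinom(n * m, 1, rep(freqs, each = n)), n, m))
  }
  if (is.null(block_id)) block_id <- rep(1L, m)
  z <- matrix(stats::rnorm(n * m), n, m)
  for (j in 2:m) {
    if (block_id[j] == block_id[j - 1]) {
      z[, j] <- rho_ld * z[, j - 1] + sqrt(1 - rho_ld^2) * z[, j]
    }
  }
  # allele = 1 where the latent falls below the frequency quantile
  sweep(z, 2, stats::qnorm(freqs), "<") * 1L
}

#' Sample parental genotypes
#'
#' Draws `n` individuals at the given allele frequencies. With `rho_ld = 0`
#' each variant is an independent `Binomial(2, p)` draw (Hardy-Weinberg).
#' With `rho_ld > 0`, haplotypes within each of `n_blocks` equal-sized blocks
#' follow a Gaussian-threshold copula with adjacent-variant correlation
#' `rho_ld`. Haplotypes are retained in `attr(, "haplotypes")` so meiosis can
#' transmit them.
#'
#' @param freqs Effect-allele frequencies in `(0, 1)`.
#' @param n Number of individuals (> 0).
#' @param rho_ld Adjacent-variant haplotype correlation in `[0, 1)`.
#' @param n_blocks Number of LD blocks.
#' @return A [genotype_matrix()] with haplotypes attached.
#' @export
sample_parent_genotypes <- function(freqs, n, rho_ld = 0, n_blocks = 1) {
  if (n <= 0) stop("n must be positive")
  if (any(freqs < 0) || any(freqs > 1)) stop("freqs must be in [0, 1]")
  m <- length(freqs)
  block_id <- sort(rep_len(seq_len(n_blocks), m))
  h1 <- sample_haplotypes(freqs, n, rho_ld, block_id)
  h2 <- sample_haplotypes(freqs, n, rho_ld, block_id)
  variants <- data.frame(variant_id = sprintf("snp%04d", seq_len(m)),
                         effect_allele = "A", other_allele = "G",
                         frequency = freqs, block_id = block_id,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(h1 + h2, variants)
  attr(gm, "haplotypes") <- list(h1 = h1, h2 = h2)
  gm
}

#' Pair mates by phenotypic similarity
#'
#' Rank-matching through a shared latent Gaussian: a couple slot `k` carries a
#' bivariate-normal draw `(u_k, v_k)` with correlation `rho_mate`; the male
#' ranked `r`-th on phenotype occupies the slot whose `u` is ranked `r`-th,
#' and likewise for females against `v`. For Gaussian phenotypes the realized
#' spousal correlation approaches `rho_mate` as the pool grows; `rho_mate = 1`
#' reduces to exact rank-sorted matching.
#'
#' @param male_phenotypes,female_phenotypes Equal-length phenotype vectors.
#' @param rho_mate Target spousal phenotype correlation in `[-1, 1]`.
#' @return Integer vector `wife`: `wife[i]` is the index of the female paired
#'   with male `i`.
#' @export
mate_assortatively <- function(male_phenotypes, female_phenotypes, rho_mate) {
  n <- length(male_phenotypes)
  if (length(female_phenotypes) != n) stop("unequal mate pool sizes")
  if (abs(rho_mate) > 1) stop("rho_mate must be in [-1, 1]")
  u <- stats::rnorm(n)
  v <- rho_mate * u + sqrt(1 - rho_mate^2) * stats::rnorm(n)
  slot_of_male <- integer(n)
  slot_of_female <- integer(n)
  slot_of_male[order(male_phenotypes)] <- order(u)      # r-th male -> r-th u slot
  slot_of_female[order(female_phenotypes)] <- order(v)
  female_in_slot <- integer(n)
  female_in_slot[slot_of_female] <- seq_len(n)
  female_in_slot[slot_of_male]
}

## split a dosage vector/matrix into two allele matrices (phase arbitrary:
## heterozygotes carry (1, 0)). Used when true haplotypes are not available.
dosage_to_haps <- function(d) {
  list(h1 = pmin(d, 1), h2 = pmax(d - 1, 0))
}

#' Mendelian transmission to a twin pair
#'
#' Each twin receives one allele per parent per locus, with the transmitted
#' haplotype chosen uniformly and independently across loci (unlinked
#' transmission). A DZ pair is two independent meioses; an MZ pair is one
#' meiosis duplicated. The transmission record stores which parental
#' haplotype (1 or 2) each twin received at each locus — for homozygous
#' parents the coin is still flipped and recorded, since identity by descent
#' concerns the transmitted chromosome, not the allele state.
#'
#' @param father_genotype,mother_genotype Dosage vectors (one family) or
#'   matrices (families x loci) with entries in `{0, 1, 2}`.
#' @param zygosity `"MZ"` or `"DZ"`, scalar or one per family.
#' @param father_haplotypes,mother_haplotypes Optional `list(h1, h2)` of
#'   phased allele matrices; derived from the dosages when absent.
#' @return List with `twin1`, `twin2` (dosages, same shape as the input) and
#'   `transmission`: matrices `pat1`, `mat1`, `pat2`, `mat2` of haplotype
#'   indices in `{1, 2}`.
#' @export
meiosis <- function(father_genotype, mother_genotype, zygosity = "DZ",
                    father_haplotypes = NULL, mother_haplotypes = NULL) {
  fg <- rbind(father_genotype)  # vectors become 1 x m matrices
  mg <- rbind(mother_genotype)
  if (!all(fg %in% 0:2) || !all(mg %in% 0:2)) {
    stop("parental dosages must be in {0, 1, 2}")
  }
  if (!all(zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  n <- nrow(fg); m <- ncol(fg)
  zygosity <- rep_len(zygosity, n)
  fh <- if (is.null(father_haplotypes)) dosage_to_haps(fg) else father_haplotypes
  mh <- if (is.null(mother_haplotypes)) dosage_to_haps(mg) else mother_haplotypes
  coin <- function() matrix(sample(c(1L, 2L), n * m, replace = TRUE), n, m)
  pat1 <- coin(); mat1 <- coin()
  pat2 <- coin(); mat2 <- coin()
  mz <- zygosity == "MZ"
  pat2[mz, ] <- pat1[mz, ]; mat2[mz, ] <- mat1[mz, ]
  pick <- function(h, idx) ifelse(idx == 1L, h$h1, h$h2)
  twin1 <- pick(fh, pat1) + pick(mh, mat1)
  twin2 <- pick(fh, pat2) + pick(mh, mat2)
  if (length(father_genotype) == m && is.null(dim(father_genotype))) {
    twin1 <- drop(twin1); twin2 <- drop(twin2)
  }
  list(twin1 = twin1, twin2 = twin2,
       transmission = list(pat1 = pat1, mat1 = mat1,
                           pat2 = pat2, mat2 = mat2))
}

#' Proportion of transmissions shared by a twin pair
#'
#' Per locus, a pair shares 0, 1 or 2 parental transmissions; the share is
#' that count over 2, averaged across loci. DZ pairs average 0.5 under
#' Mendelian transmission ("sharing on average 50% of their genes"); MZ pairs
#' return exactly 1.
#'
#' @param transmission The `transmission` element returned by [meiosis()].
#' @return Numeric vector of per-pair shared proportions in `[0, 1]`.
#' @export
ibd_share <- function(transmission) {
  tr <- transmission
  if (is.null(tr$pat1) || length(tr$pat1) == 0) stop("empty transmission record")
  match_mat <- (tr$pat1 == tr$pat2) + (tr$mat1 == tr$mat2)
  if (is.null(dim(match_mat))) return(mean(match_mat) / 2)
  rowMeans(match_mat) / 2
}

#' Simulate the twin phenotype
#'
#' `y = delta * g_child + eta * g_midparent + shift[subpop] + c_family + e`,
#' with `c_family ~ N(0, sigma_c^2)` shared by co-twins and independent noise
#' `e`. The noise SD is set so the total phenotypic variance is 1, using the
#' empirical variance of the systematic part; if the stated components
#' already exceed unit variance the call fails with the component budget.
#'
#' @param child_true_pgs Standardized true genetic values, one per individual.
#' @param midparent_true_pgs Standardized mid-parent genetic values, one per
#'   individual (identical for co-twins).
#' @param subpop Integer subpopulation index per individual.
#' @param family_shared_env Shared-environment value per individual
#'   (identical for co-twins), typically `N(0, sigma_c^2)` draws.
#' @param config A [sim_config()].
#' @return Phenotype vector with attribute `sigma_e`.
#' @export
simulate_phenotype <- function(child_true_pgs, midparent_true_pgs, subpop,
                               family_shared_env, config) {
  shifts <- rep_len(config$stratum_effect, config$n_subpops)
  systematic <- config$delta * child_true_pgs +
    config$eta * midparent_true_pgs + shifts[subpop]
  var_sys <- if (length(systematic) > 1) stats::var(systematic) else 0
  var_e <- 1 - var_sys - config$sigma_c^2
  if (var_e <= 0) {
    stop(sprintf(paste0("phenotype variance budget exceeded: systematic ",
                        "%.3f + shared env %.3f >= 1"),
                 var_sys, config$sigma_c^2))
  }
  y <- systematic + family_shared_env +
    stats::rnorm(length(systematic), 0, sqrt(var_e))
  attr(y, "sigma_e") <- sqrt(var_e)
  y
}

#' Simulate family-environment items
#'
#' A latent family enrichment score
#' `loading * g_midparent + sqrt(1 - loading^2) * noise` drives four items of
#' the kind used to index a musically enriched childhood home: two counts
#' (records in the home, people playing an instrument; Poisson with a
#' log-link on the latent), an ordinal concert-attendance frequency (0-4, by
#' thresholding), and a binary music-education-before-12 indicator. Items are
#' family-level: identical for both co-twins.
#'
#' @param midparent_true_pgs Standardized mid-parent genetic value per family.
#' @param enrichment_loading Loading in `[0, 1]`.
#' @return Data frame with `family_id`, `n_records`, `n_players`,
#'   `concert_freq`, `music_edu_before12`; the latent score is attached as
#'   `attr(, "latent")`.
#' @export
simulate_environment_items <- function(midparent_true_pgs,
                                       enrichment_loading = 0.5) {
  if (enrichment_loading < 0 || enrichment_loading > 1) {
    stop("enrichment_loading must be in [0, 1]")
  }
  n <- length(midparent_true_pgs)
  latent <- enrichment_loading * midparent_true_pgs +
    sqrt(1 - enrichment_loading^2) * stats::rnorm(n)
  out <- data.frame(
    family_id = sprintf("F%05d", seq_len(n)),
    n_records = stats::rpois(n, exp(2.5 + 0.4 * latent)),
    n_players = stats::rpois(n, exp(0.5 + 0.5 * latent)),
    concert_freq = findInterval(latent + stats::rnorm(n, 0, 0.8),
                                c(-1, -0.2, 0.6, 1.4)),
    music_edu_before12 = as.integer(latent + stats::rnorm(n, 0, 0.8) > 0.3),
    stringsAsFactors = FALSE)
  attr(out, "latent") <- latent
  out
}

#' Simulate a twin-family study
#'
#' End-to-end generator: ancestral frequencies; Balding-Nichols subpopulation
#' divergence; parental pools per subpopulation; phenotypic assortative
#' mating; Mendelian transmission to MZ/DZ twin pairs; true per-variant
#' effects `N(0, h2_true / M)` on the standardized genotype scale plus
#' noisy "GWAS" weights; the additive phenotype model of
#' [simulate_phenotype()]; and family-environment items. Genetic values are
#' standardized within each generation (the scale on which `delta` and `eta`
#' are expressed).
#'
#' @param config A [sim_config()].
#' @return Object of class `twin_sim`: a list with `config`, `genotypes`
#'   (twins), `parent_genotypes`, `pedigree`, `phenotypes`,
#'   `environment_items`, `weights` (noisy GWAS weights as a [WeightSet
#'   data frame][read_weights]), `true_weights`, `true_g` (children),
#'   `midparent_g`, `transmission`, and `spousal_phenotype_r` /
#'   `spousal_pgs_r` (realized mating correlations).
#' @export
simulate_twin_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families; m <- config$n_snps
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  fsub <- draw_subpop_frequencies(p0, config$fst, config$n_subpops)
  subpop <- rep_len(seq_len(config$n_subpops), nf)

  w_true <- stats::rnorm(m, 0, sqrt(config$h2_true / m))
  w_gwas <- w_true + stats::rnorm(m, 0, config$gwas_noise_sd)
  # genetic value on the ancestral standardized-genotype scale
  gvalue <- function(d) drop(scale(d, center = 2 * p0,
                                   scale = sqrt(2 * p0 * (1 - p0))) %*% w_true)

  fathers <- mothers <- vector("list", config$n_subpops)
  fam_of <- split(seq_len(nf), subpop)
  father_dos <- mother_dos <- matrix(0L, nf, m)
  father_h <- mother_h <- NULL
  if (config$rho_ld > 0) {
    father_h <- mother_h <- list(h1 = matrix(0L, nf, m), h2 = matrix(0L, nf, m))
  }
  for (k in seq_len(config$n_subpops)) {
    idx <- fam_of[[as.character(k)]]
    nk <- length(idx)
    fg <- sample_parent_genotypes(fsub[k, ], nk, config$rho_ld, config$n_blocks)
    mg <- sample_parent_genotypes(fsub[k, ], nk, config$rho_ld, config$n_blocks)
    g_f <- gvalue(fg$dosages); g_m <- gvalue(mg$dosages)
    sd_ref <- sqrt(config$h2_true)  # population SD of the raw genetic value
    shifts <- rep_len(config$stratum_effect, config$n_subpops)
    noise_sd <- sqrt(max(1 - config$delta^2, 0.05))
    y_f <- config$delta * g_f / sd_ref + shifts[k] + stats::rnorm(nk, 0, noise_sd)
    y_m <- config$delta * g_m / sd_ref + shifts[k] + stats::rnorm(nk, 0, noise_sd)
    wife <- mate_assortatively(y_f, y_m, config$rho_mate)
    father_dos[idx, ] <- fg$dosages
    mother_dos[idx, ] <- mg$dosages[wife, , drop = FALSE]
    if (config$rho_ld > 0) {
      fh <- attr(fg, "haplotypes"); mh <- attr(mg, "haplotypes")
      father_h$h1[idx, ] <- fh$h1; father_h$h2[idx, ] <- fh$h2
      mother_h$h1[idx, ] <- mh$h1[wife, , drop = FALSE]
      mother_h$h2[idx, ] <- mh$h2[wife, , drop = FALSE]
    }
  }

  zyg <- ifelse(stats::runif(nf) < config$prop_mz, "MZ", "DZ")
  mei <- meiosis(father_dos, mother_dos, zyg, father_h, mother_h)

  g1 <- gvalue(mei$twin1); g2 <- gvalue(mei$twin2)
  g_child_raw <- c(rbind(g1, g2))           # interleaved T1, T2 per family
  mu_c <- mean(g_child_raw); sd_c <- stats::sd(g_child_raw)
  g1s <- (g1 - mu_c) / sd_c; g2s <- (g2 - mu_c) / sd_c
  gmid_raw <- (gvalue(father_dos) + gvalue(mother_dos)) / 2
  gmid <- drop(scale(gmid_raw))

  c_fam <- stats::rnorm(nf, 0, config$sigma_c)
  child_g <- c(rbind(g1s, g2s))
  child_gmid <- rep(gmid, each = 2)
  child_sub <- rep(subpop, each = 2)
  child_cfam <- rep(c_fam, each = 2)
  y <- simulate_phenotype(child_g, child_gmid, child_sub, child_cfam, config)

  fam_id <- sprintf("F%05d", seq_len(nf))
  t1 <- paste0(fam_id, "_T1"); t2 <- paste0(fam_id, "_T2")
  sex1 <- ifelse(stats::runif(nf) < 0.5, "F", "M")
  sex2 <- ifelse(zyg == "MZ", sex1, ifelse(stats::runif(nf) < 0.5, "F", "M"))
  age <- round(stats::runif(nf, 27, 54))

  pedigree <- data.frame(family_id = fam_id,
                         father_id = paste0(fam_id, "_FA"),
                         mother_id = paste0(fam_id, "_MO"),
                         twin1_id = t1, twin2_id = t2,
                         zygosity = zyg, subpop = subpop,
                         stringsAsFactors = FALSE)
  phenotypes <- data.frame(
    sample_id = c(rbind(t1, t2)),
    family_id = rep(fam_id, each = 2),
    zygosity = rep(zyg, each = 2),
    sex = c(rbind(sex1, sex2)),
    age = rep(age, each = 2),
    phenotype = as.numeric(y),
    stringsAsFactors = FALSE)

  env <- simulate_environment_items(gmid, config$enrichment_loading)
  env$family_id <- fam_id

  variants <- data.frame(variant_id = sprintf("snp%04d", seq_len(m)),
                         effect_allele = "A", other_allele = "G",
                         frequency = p0,
                         block_id = sort(rep_len(seq_len(config$n_blocks), m)),
                         stringsAsFactors = FALSE)
  child_dos <- matrix(0L, 2 * nf, m)
  child_dos[seq(1, 2 * nf, by = 2), ] <- mei$twin1
  child_dos[seq(2, 2 * nf, by = 2), ] <- mei$twin2
  genotypes <- genotype_matrix(child_dos, variants, c(rbind(t1, t2)))
  parent_dos <- rbind(father_dos, mother_dos)
  parents <- genotype_matrix(parent_dos, variants,
                             c(pedigree$father_id, pedigree$mother_id))

  weights <- data.frame(variant_id = variants$variant_id,
                        effect_allele = variants$effect_allele,
                        other_allele = variants$other_allele,
                        effect_weight = w_gwas, stringsAsFactors = FALSE)
  attr(weights, "provenance") <- "marginal"

  # realized spousal correlations (emergent quantities, reported not imposed)
  gf <- gvalue(father_dos); gm2 <- gvalue(mother_dos)
  spousal_pgs_r <- if (nf > 2) stats::cor(gf, gm2) else NA_real_

  structure(list(config = config, genotypes = genotypes,
                 parent_genotypes = parents, pedigree = pedigree,
                 phenotypes = phenotypes, environment_items = env,
                 weights = weights,
                 true_weights = w_true, true_g = child_g,
                 midparent_g = gmid, transmission = mei$transmission,
                 spousal_pgs_r = spousal_pgs_r),
            class = "twin_sim")
}

#' @export
print.twin_sim <- function(x, ...) {
  nf <- x$config$n_families
  cat("twin_sim:", nf, "families (",
      sum(x$pedigree$zygosity == "MZ"), "MZ /",
      sum(x$pedigree$zygosity == "DZ"), "DZ ),",
      x$config$n_snps, "variants,",
      x$config$n_subpops, "subpopulation(s)\n")
  cat(sprintf("  delta = %.2f, eta = %.2f, sigma_c = %.2f, rho_mate = %.2f, fst = %.3f\n",
              x$config$delta, x$config$eta, x$config$sigma_c,
              x$config$rho_mate, x$config$fst))
  if (!is.na(x$spousal_pgs_r)) {
    cat(sprintf("  realized spousal genetic-value correlation: %.3f\n",
                x$spousal_pgs_r))
  }
  invisible(x)
}

#' Simulate item-level phenotype data from a twin study
#'
#' Expands the latent phenotype of a [simulate_twin_study()] object into the
#' item-level measures the scoring functions consume: three discrimination
#' subtests (pitch 0-27, melody 0-18, rhythm 0-18, binomial around a
#' logistic link on the latent ability), six tapping trials of inter-tap
#' intervals whose coefficient of variation falls with ability, and four
#' flow-proneness subscale means (work, leisure, maintenance, music) on a
#' 1-5 scale, with only the music subscale tied to the latent phenotype.
#'
#' @param sim A `twin_sim` object.
#' @param taps_per_trial Number of self-paced intervals per tapping trial.
#' @return List of data frames `smdt`, `isip`, `flow`, each keyed by
#'   `sample_id`.
#' @export
simulate_item_phenotypes <- function(sim, taps_per_trial = 25) {
  ph <- sim$phenotypes
  n <- nrow(ph)
  ability <- ph$phenotype
  rb <- function(size, shift) {
    stats::rbinom(n, size, stats::plogis(shift + 0.8 * (ability + stats::rnorm(n, 0, 0.6))))
  }
  smdt <- data.frame(sample_id = ph$sample_id,
                     pitch = rb(27, 0.4), melody = rb(18, 0.2),
                     rhythm = rb(18, 0.2), stringsAsFactors = FALSE)
  targets <- c(524, 819, 655, 1024, 655, 524)
  cv <- exp(-2.6 - 0.25 * ability + stats::rnorm(n, 0, 0.25))
  isip <- do.call(rbind, lapply(seq_along(targets), function(tr) {
    data.frame(sample_id = rep(ph$sample_id, each = taps_per_trial),
               trial = tr,
               interval = stats::rnorm(n * taps_per_trial,
                                       mean = rep(targets[tr], n * taps_per_trial),
                                       sd = rep(cv * targets[tr], each = taps_per_trial)),
               stringsAsFactors = FALSE)
  }))
  clamp15 <- function(x) pmin(pmax(x, 1), 5)
  flow <- data.frame(sample_id = ph$sample_id,
                     work = clamp15(round(stats::rnorm(n, 3, 0.8), 1)),
                     leisure = clamp15(round(stats::rnorm(n, 3.2, 0.8), 1)),
                     maintenance = clamp15(round(stats::rnorm(n, 2.8, 0.8), 1)),
                     music = clamp15(round(stats::rnorm(n, 3 + 0.3 * ability, 0.8), 1)),
                     stringsAsFactors = FALSE)
  list(smdt = smdt, isip = isip, flow = flow)
}

#' Write simulated study data to disk
#'
#' Emits the study's file interfaces: genotypes (dosage TSV or VCF with
#' parents and twins), pedigree TSV, phenotype TSV, environment-items TSV and
#' a PGS-catalog-style weights TSV.
#'
#' @param sim A `twin_sim` object.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"vcf"` for the genotypes.
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_data <- function(sim, dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_g <- genotype_matrix(rbind(sim$parent_genotypes$dosages,
                                 sim$genotypes$dosages),
                           sim$genotypes$variants,
                           c(sim$parent_genotypes$sample_ids,
                             sim$genotypes$sample_ids))
  geno_path <- file.path(dir, if (format == "vcf") "genotypes.vcf"
                              else "genotypes.tsv")
  write_genotypes(all_g, geno_path, format)
  paths <- c(genotypes = geno_path,
             pedigree = file.path(dir, "pedigree.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             environment = file.path(dir, "environment.tsv"),
             weights = file.path(dir, "weights.tsv"))
  utils::write.table(sim$pedigree, paths["pedigree"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$environment_items, paths["environment"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_weights(sim$weights, paths["weights"])
  invisible(paths)
}
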