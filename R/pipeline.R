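#' Run the full family-PGS pipeline
#'
#' One-call orchestration of the study design: simulate a twin cohort (or
#' load previously written files), derive ancestry PCs (MAF filter, LD
#' prune, PCA), compute polygenic scores (optionally SBLUP-reweighted using
#' per-block LD estimated from the parental genotypes), impute MZ co-twin
#' scores, build the composite outcomes from item-level data, run the
#' covariate-adjusted cluster-robust association for every outcome, fit the
#' within/between-family decomposition on complete DZ pairs, and emit the
#' gene-environment / confounding diagnostics.
#'
#' The `config` is a list (or a YAML/JSON file) with blocks:
#' \describe{
#'   \item{seed}{integer; drives every random step.}
#'   \item{sim}{fields of [sim_config()].}
#'   \item{analysis}{`n_pcs` (default 10), `alpha` (0.05), `sblup`
#'     (FALSE), `same_sex_only` (FALSE), `maf_threshold` (0.05),
#'     `ld_r2` (0.1), and an optional `gwas` block `h2_snp`/`M`/`N` for
#'     [expected_r2()].}
#' }
#'
#' @param config List, or path to a YAML or JSON config file.
#' @param out_dir Output directory; created if needed.
#' @param format Genotype output format, `"tsv"` or `"vcf"`.
#' @return Invisibly, a list with `association` (data frame),
#'   `decomposition` (data frame), `diagnostics` (list), `files` (paths).
#'   Written artifacts: `association.tsv`, `decomposition.tsv`,
#'   `diagnostics.json`, `run.log` and the simulated data files.
#' @export
run_pipeline <- function(config, out_dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(config$seed %||% 1L)
  ana <- config$analysis %||% list()
  n_pcs <- ana$n_pcs %||% 10L
  alpha <- ana$alpha %||% 0.05
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logf <- function(...) {
    line <- sprintf(...)
    writeLines(line, log_con)
    message(line)
  }
  logf("fampgs %s | seed %d", as.character(utils::packageVersion("fampgs")),
       seed)

  sim_args <- config$sim %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_twin_study(scfg)
  logf("simulate: %d families, %d variants, %d MZ / %d DZ pairs",
       scfg$n_families, scfg$n_snps, sum(sim$pedigree$zygosity == "MZ"),
       sum(sim$pedigree$zygosity == "DZ"))
  files <- write_sim_data(sim, out_dir, format)

  set.seed(seed + 1L)  # analysis-stage randomness separated from the sim's
  gm <- sim$genotypes
  gq <- maf_filter(gm, ana$maf_threshold %||% 0.05)
  gq <- ld_prune(gq, ana$ld_r2 %||% 0.1)
  logf("genotools: %d variants after MAF filter + LD pruning (from %d)",
       ncol(gq$dosages), ncol(gm$dosages))
  n_pcs_used <- min(n_pcs, ncol(gq$dosages), length(gq$sample_ids) - 1L)
  pcs <- pca_components(gq, n_pcs_used)
  logf("pca: %d components extracted", n_pcs_used)

  weights <- sim$weights
  if (isTRUE(ana$sblup)) {
    blocks <- split(sim$genotypes$variants$variant_id,
                    sim$genotypes$variants$block_id)
    ld <- lapply(blocks, function(ids) {
      stats::cor(sim$parent_genotypes$dosages[, ids, drop = FALSE])
    })
    meta <- pipeline_gwas_meta(config, scfg)
    weights <- sblup_reweight(weights, ld, meta)
    logf("sblup: weights re-estimated over %d LD blocks (kappa = %.4g)",
         length(ld), meta$M * (1 / meta$h2_snp - 1) / meta$N)
  }
  scores <- compute_pgs(gm, weights)
  scores <- impute_mz_pgs(scores, sim$pedigree)
  logf("pgs: %d samples scored, %d MZ co-twin scores imputed",
       length(scores), attr(scores, "n_imputed"))

  items <- simulate_item_phenotypes(sim)
  apt <- aptitude_composite(items$smdt)
  mt <- isip_scores(items$isip)
  flow <- items$flow
  flow$global_flow <- global_flow(flow$work, flow$leisure, flow$maintenance)

  d <- sim$phenotypes
  d$pgs <- scores[d$sample_id]
  d <- merge(d, apt, by = "sample_id")
  d <- merge(d, mt, by = "sample_id")
  d <- merge(d, flow[, c("sample_id", "music", "global_flow")],
             by = "sample_id")
  names(d)[names(d) == "music"] <- "music_flow"
  pc_df <- data.frame(sample_id = rownames(pcs$scores), pcs$scores,
                      stringsAsFactors = FALSE)
  d <- merge(d, pc_df, by = "sample_id")
  d <- d[order(d$family_id, d$sample_id), ]

  pc_names <- paste0("PC", seq_len(n_pcs_used))
  exempt <- c("age", pc_names)
  d$sex_num <- as.integer(d$sex == "M")
  outcomes <- c("phenotype", "aptitude", "motor_timing", "music_flow",
                "global_flow")
  std <- standardize_columns(d[, c(outcomes, "pgs")], exempt_columns = NULL)
  ds <- d
  ds[, c(outcomes, "pgs")] <- std

  covars <- c("sex_num", "age", pc_names)
  assoc_rows <- lapply(outcomes, function(oc) {
    a <- pgs_association(ds, oc, pgs = "pgs", covariates = covars,
                         cluster = "family_id")
    data.frame(outcome = oc, beta = a$beta, se = a$se, p = a$p,
               delta_r2 = a$delta_r2, n = a$n, n_clusters = a$n_clusters,
               stringsAsFactors = FALSE)
  })
  assoc_tab <- do.call(rbind, assoc_rows)
  logf("assoc: %d outcomes analysed, n = %d in %d families",
       nrow(assoc_tab), assoc_tab$n[1], assoc_tab$n_clusters[1])

  ped <- sim$pedigree
  if (isTRUE(ana$same_sex_only)) {
    sex_of <- stats::setNames(ds$sex, ds$sample_id)
    same <- sex_of[ped$twin1_id] == sex_of[ped$twin2_id]
    ped <- ped[same, , drop = FALSE]
    logf("decompose: restricted to %d same-sex pairs", nrow(ped))
  }
  dec <- decompose_pgs(stats::setNames(ds$pgs, ds$sample_id), ped)
  dd <- merge(dec, ds[, c("sample_id", outcomes, "sex_num", pc_names)],
              by = "sample_id")
  decomp_rows <- lapply(c("phenotype", "aptitude"), function(oc) {
    fit <- fit_family_decomp(dd, oc, covariates = c("sex_num", pc_names))
    data.frame(outcome = oc, effect = c("Between", "Within"),
               beta = c(fit$beta_between, fit$beta_within),
               se = c(fit$se_between, fit$se_within),
               p = fit$coefficients$p[match(c(fit$between, fit$within),
                                            fit$coefficients$term)],
               ci_low = c(fit$ci95_between[1], fit$ci95_within[1]),
               ci_high = c(fit$ci95_between[2], fit$ci95_within[2]),
               n_pairs = fit$n_pairs, stringsAsFactors = FALSE)
  })
  decomp_tab <- do.call(rbind, decomp_rows)
  logf("decompose: %d complete DZ pairs", decomp_tab$n_pairs[1])

  env_idx <- environment_index(sim$environment_items)
  ds2 <- merge(ds, env_idx, by = "family_id")
  ge <- pearson_r_ci(ds2$enrichment_index, ds2$pgs)
  dzr <- dz_pgs_correlation(stats::setNames(ds$pgs, ds$sample_id),
                            sim$pedigree)
  meta <- pipeline_gwas_meta(config, scfg)
  diagnostics <- list(
    ge_correlation = unclass(ge)[c("r", "n", "ci_low", "ci_high", "p")],
    dz_pgs_correlation = c(unclass(dzr)[c("r", "n", "ci_low", "ci_high",
                                          "p", "contains_half")],
                           list(verdict = test_expected_half(dzr))),
    expected_r2 = list(h2_snp = meta$h2_snp, M = meta$M, N = meta$N,
                       value = expected_r2(meta)),
    alpha = alpha, schema_version = 1L)
  logf("diagnose: GE r = %.3f; DZ co-twin PGS r = %.3f (%s)",
       ge$r, dzr$r, diagnostics$dz_pgs_correlation$verdict)

  files <- c(files,
             association = file.path(out_dir, "association.tsv"),
             decomposition = file.path(out_dir, "decomposition.tsv"),
             diagnostics = file.path(out_dir, "diagnostics.json"),
             env_index = file.path(out_dir, "environment_index.tsv"),
             log = log_path)
  utils::write.table(assoc_tab, files["association"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(decomp_tab, files["decomposition"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(env_idx, files["env_index"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(diagnostics, files["diagnostics"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(association = assoc_tab, decomposition = decomp_tab,
                 diagnostics = diagnostics, files = files))
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

pipeline_gwas_meta <- function(config, scfg) {
  g <- (config$analysis %||% list())$gwas %||% list()
  gwas_meta(h2_snp = g$h2_snp %||% scfg$h2_true,
            M = g$M %||% scfg$n_snps,
            N = g$N %||% 1e5)
}

#' Forest plot of PGS association estimates
#'
#' Simple base-graphics forest plot of the per-outcome standardized PGS
#' effects with cluster-robust 95% CIs, the machine version of the study's
#' headline association figure.
#'
#' @param association Association table from [run_pipeline()] (columns
#'   `outcome`, `beta`, `se`).
#' @param level Confidence level.
#' @return Invisibly, the plotted table.
#' @export
plot_association_forest <- function(association, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  lo <- association$beta - q * association$se
  hi <- association$beta + q * association$se
  k <- nrow(association)
  graphics::plot(association$beta, k:1, xlim = range(c(lo, hi, 0)),
                 yaxt = "n", ylab = "", xlab = "standardized PGS effect",
                 pch = 19)
  graphics::axis(2, at = k:1, labels = association$outcome, las = 1)
  graphics::segments(lo, k:1, hi, k:1)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(association)
}
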