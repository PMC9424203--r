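# shared fixture builders, all generated in code

# genotype matrix with given dosage columns (list of vectors)
toy_gm <- function(..., effect = "A", other = "G") {
  cols <- list(...)
  d <- do.call(cbind, cols)
  variants <- data.frame(variant_id = sprintf("v%02d", seq_along(cols)),
                         effect_allele = rep_len(effect, length(cols)),
                         other_allele = rep_len(other, length(cols)),
                         stringsAsFactors = FALSE)
  genotype_matrix(d, variants, sprintf("S%03d", seq_len(nrow(d))))
}

toy_pedigree <- function(n, zygosity = "DZ") {
  fam <- sprintf("F%03d", seq_len(n))
  data.frame(family_id = fam,
             father_id = paste0(fam, "_FA"), mother_id = paste0(fam, "_MO"),
             twin1_id = paste0(fam, "_T1"), twin2_id = paste0(fam, "_T2"),
             zygosity = rep_len(zygosity, n), subpop = 1L,
             stringsAsFactors = FALSE)
}

toy_weights <- function(m, w = NULL, effect = "A", other = "G") {
  data.frame(variant_id = sprintf("v%02d", seq_len(m)),
             effect_allele = rep_len(effect, m),
             other_allele = rep_len(other, m),
             effect_weight = if (is.null(w)) rep(1, m) else w,
             stringsAsFactors = FALSE)
}

# paired twin data with a family random intercept, for decomposition tests:
# y = bw * within + bb * between + family intercept + noise
toy_pair_data <- function(n_pairs, bw, bb, sd_fam = 0.3, sd_e = 0.7,
                          seed = 1) {
  set.seed(seed)
  fam <- rep(sprintf("F%04d", seq_len(n_pairs)), each = 2)
  s <- rnorm(2 * n_pairs)
  sm <- ave(s, fam)
  within <- s - sm
  gam <- rep(rnorm(n_pairs, 0, sd_fam), each = 2)
  y <- bw * within + bb * sm + gam + rnorm(2 * n_pairs, 0, sd_e)
  data.frame(family_id = fam, y = y, pgs_within = within, pgs_between = sm,
             sex_num = rep(rbinom(n_pairs, 1, 0.5), each = 2),
             stringsAsFactors = FALSE)
}
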