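# Shared fixtures, built in code at test time.

small_panel <- function() {
  snp_panel(
    snp_id = c("rs_one", "rs_two", "rs_three"),
    gene = c("G1", "G2", "G3"),
    major_allele = c("C", "T", "G"),
    minor_allele = c("A", "A", "C"),
    effect_allele = c("A", "T", "G"),
    weight = c(0.1, 0.2, 0.3),
    maf = c(0.3, 0.1, 0.45)
  )
}

# All generator effects switched off: the null scenario.
null_config <- function(n_subjects = 599, seed = 1L, ...) {
  cohort_config(
    n_subjects = n_subjects, seed = seed,
    beta_tl_per_effect_allele = 0,
    beta_sperm_per_logTL = 0,
    age_betas = stats::setNames(rep(0, 9), names(default_age_betas())),
    ...
  )
}

# Genotype tibble with a prescribed number of missing calls per subject,
# on the full 11-SNP default panel.
genotypes_with_missing <- function(n_missing_per_subject, seed = 42) {
  panel <- default_tel_panel()
  g <- simulate_genotypes(panel, length(n_missing_per_subject),
                          missing_rate = 0, seed = seed)
  set.seed(seed + 1)
  for (i in seq_along(n_missing_per_subject)) {
    k <- n_missing_per_subject[i]
    if (k > 0) {
      cols <- sample(panel$snp_id, k)
      g[i, cols] <- NA_character_
    }
  }
  g
}
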