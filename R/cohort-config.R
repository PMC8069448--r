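#' Configuration for the synthetic cohort generator
#'
#' Collects, validates and defaults every knob of the generative model used by
#' [simulate_cohort()]. Defaults emulate the structure of a consecutive
#' andrology cohort of 599 men (ages 18-59, about a third smokers), genotyped
#' on an 11-SNP telomere panel with ~2% per-genotype missingness, with sperm
#' telomere length measured by qPCR in triplicate against per-plate standard
#' curves.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer master seed. Every stage derives its own sub-seed from
#'   it, so stages are independently reproducible.
#' @param missing_rate Per-genotype missingness probability.
#' @param beta_tl_per_effect_allele Additive effect of one effect allele on the
#'   latent natural-log telomere ratio.
#' @param sigma_tl SD of the latent log telomere ratio around its genetic mean.
#' @param age_range Numeric length-2, youngest and oldest admissible age in
#'   years; ages are drawn from a normal truncated to this range.
#' @param age_mean,age_sd Location and scale of the (untruncated) age draw.
#' @param age_betas Named numeric vector: change of each semen parameter per
#'   year of age, in the parameter's own units. Defaults follow the magnitudes
#'   seen in clinical cohorts (motility and morphology decline with age).
#' @param beta_sperm_per_logTL Effect of the latent log telomere ratio on every
#'   semen parameter; the default 0 makes telomere length and semen quality
#'   independent, the null scenario used for calibration.
#' @param smoking_prevalence Probability that a subject smokes.
#' @param n_plates Number of qPCR plates; `NULL` sizes plates to 13 subjects
#'   each (6 sample wells per subject plus a 14-well pair of standard curves
#'   fills a 96-well plate).
#' @param plate_sd SD (cycles) of per-plate, per-target Ct offsets.
#' @param ct_sd SD (cycles) of well-level replicate noise.
#' @param efficiency_tel,efficiency_alb True amplification efficiencies of the
#'   telomere and albumin reactions, in `(1, 2]`.
#' @param sperm_params Data frame describing the semen-parameter generative
#'   model (columns `parameter`, `mean`, `sd`, `lower`, `upper`); means are the
#'   population means at the mean age. See [default_sperm_params()].
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 599,
                          seed = 1L,
                          missing_rate = 0.02,
                          beta_tl_per_effect_allele = 0.05,
                          sigma_tl = 0.3,
                          age_range = c(18, 59),
                          age_mean = 34.8,
                          age_sd = 7.5,
                          age_betas = default_age_betas(),
                          beta_sperm_per_logTL = 0,
                          smoking_prevalence = 0.32,
                          n_plates = NULL,
                          plate_sd = 0.15,
                          ct_sd = 0.15,
                          efficiency_tel = 1.9,
                          efficiency_alb = 2.0,
                          sperm_params = default_sperm_params()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  probs <- c(missing_rate = missing_rate, smoking_prevalence = smoking_prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop("missing_rate and smoking_prevalence must be in [0, 1]", call. = FALSE)
  }
  sds <- c(sigma_tl, plate_sd, ct_sd, age_sd, sperm_params$sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  effs <- c(efficiency_tel, efficiency_alb)
  if (any(effs <= 1 | effs > 2)) {
    stop("amplification efficiencies must be in (1, 2]", call. = FALSE)
  }
  if (is.null(n_plates)) n_plates <- max(1L, ceiling(n_subjects / 13))
  if (n_plates < 1) stop("n_plates must be >= 1", call. = FALSE)
  defaults <- default_age_betas()
  missing_beta <- setdiff(names(defaults), names(age_betas))
  age_betas <- c(age_betas, defaults[missing_beta])[names(defaults)]
  structure(list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    missing_rate = missing_rate,
    beta_tl_per_effect_allele = beta_tl_per_effect_allele,
    sigma_tl = sigma_tl,
    age_range = age_range,
    age_mean = age_mean,
    age_sd = age_sd,
    age_betas = age_betas,
    beta_sperm_per_logTL = beta_sperm_per_logTL,
    smoking_prevalence = smoking_prevalence,
    n_plates = as.integer(n_plates),
    plate_sd = plate_sd,
    ct_sd = ct_sd,
    efficiency_tel = efficiency_tel,
    efficiency_alb = efficiency_alb,
    sperm_params = sperm_params
  ), class = "cohort_config")
}

#' Default per-year age slopes of the semen parameters
#'
#' Units are the parameter's own units per year of age. Motility and
#' morphology decline with age; concentration and count are essentially flat.
#'
#' @return Named numeric vector, one entry per semen parameter.
#' @export
default_age_betas <- function() {
  c(concentration = 0.23,
    total_number = 0.12,
    progressive_motility = -0.31,
    nonprogressive_motility = 0.06,
    total_motility = -0.28,
    normal_morphology = -0.10,
    normal_acrosome = -0.08,
    normal_head = -0.13,
    normal_flagellum = -0.15)
}

#' Default marginal distribution of the semen parameters
#'
#' Population means (at the mean age) and residual SDs of the nine semen
#' parameters, with the truncation range of each: percentages live in
#' `[0, 100]`, concentration (10^6/mL) and total number (10^6) in `[0, Inf)`.
#'
#' @return Tibble with columns `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @export
default_sperm_params <- function() {
  tibble::tibble(
    parameter = names(default_age_betas()),
    mean = c(55.4, 180, 45.9, 5.0, 48.3, 7.4, 60, 55, 65),
    sd = c(49, 150, 18, 3, 17, 4.3, 15, 15, 15),
    lower = 0,
    upper = c(Inf, Inf, 100, 100, 100, 100, 100, 100, 100)
  )
}

# Stage-specific sub-seed derived from the master seed; stays inside the
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647L)
}
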