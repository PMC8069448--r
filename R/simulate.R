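#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws, for each panel SNP independently, genotypes at the Hardy-Weinberg
#' proportions p^2 / 2pq / q^2 implied by its minor-allele frequency, then
#' masks each call independently with probability `missing_rate`. Calls are
#' written as unordered allele pairs (`"C/A"`), the format used by the
#' genotype table on disk.
#'
#' @param panel A [snp_panel()].
#' @param n_subjects Number of subjects to simulate.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed; the draw is deterministic given it.
#'
#' @return A tibble with `subject_id` and one character column per SNP;
#'   missing calls are `NA`.
#' @export
simulate_genotypes <- function(panel, n_subjects, missing_rate = 0, seed = 1L) {
  panel <- validate_panel(panel)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  out <- list(subject_id = subject_ids(n_subjects))
  for (i in seq_len(nrow(panel))) {
    q <- panel$maf[i]
    p <- 1 - q
    geno <- c(paste(panel$major_allele[i], panel$major_allele[i], sep = "/"),
              paste(panel$major_allele[i], panel$minor_allele[i], sep = "/"),
              paste(panel$minor_allele[i], panel$minor_allele[i], sep = "/"))
    calls <- sample(geno, n_subjects, replace = TRUE,
                    prob = c(p^2, 2 * p * q, q^2))
    if (missing_rate > 0) {
      calls[stats::runif(n_subjects) < missing_rate] <- NA_character_
    }
    out[[panel$snp_id[i]]] <- calls
  }
  tibble::as_tibble(out)
}

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate the latent log telomere ratio
#'
#' The latent value is an additive-allele model:
#' `latent = intercept + beta * (total effect-allele count) + N(0, sigma_tl)`.
#' Missing genotypes contribute their expected dosage (twice the effect-allele
#' frequency) to the count -- an imputation used only for generation, never for
#' scoring. The intercept centres the population mean at zero so that the
#' latent value reads as a log ratio against a typical sample.
#'
#' @param genotypes Genotype tibble from [simulate_genotypes()].
#' @param panel The matching [snp_panel()].
#' @param beta_tl_per_effect_allele Effect of one effect allele on the latent
#'   log telomere ratio.
#' @param sigma_tl Residual SD of the latent value.
#' @param seed Integer seed.
#'
#' @return Tibble with `subject_id` and `latent_log_tl`.
#' @export
simulate_latent_tl <- function(genotypes, panel, beta_tl_per_effect_allele,
                               sigma_tl, seed = 1L) {
  panel <- validate_panel(panel)
  set.seed(seed)
  dos <- encode_additive(genotypes, panel)
  dmat <- as.matrix(dos[panel$snp_id])
  f <- effect_allele_freq(panel)
  expected <- matrix(2 * f, nrow(dmat), ncol(dmat), byrow = TRUE)
  dmat[is.na(dmat)] <- expected[is.na(dmat)]
  total <- rowSums(dmat)
  intercept <- -beta_tl_per_effect_allele * sum(2 * f)
  latent <- intercept + beta_tl_per_effect_allele * total +
    stats::rnorm(nrow(dmat), 0, sigma_tl)
  tibble::tibble(subject_id = genotypes$subject_id, latent_log_tl = latent)
}

# Ct intercepts at the 5 ng calibrator input. The telomere repeat is highly
# abundant, so its Ct sits far below the single-copy albumin Ct.
.ct_intercepts <- c(TEL = 12, ALB = 25)

# 1:2 dilution series, 20 ng down to 0.3125 ng.
.standard_masses <- 20 * 0.5^(0:6)

#' Simulate qPCR plates
#'
#' Lays each subject's telomere (TEL) and albumin (ALB) triplicates on one
#' plate (subjects are dealt round-robin across plates) and adds to every
#' plate a 7-point 1:2 dilution standard curve (20 ng to 0.3125 ng) for both
#' targets. The well model is
#' `Ct = intercept(target) + plate offset - log_E(relative input) + N(0, ct_sd)`:
#' for a standard well the relative input is `mass / 5 ng`; for a sample TEL
#' well it is `exp(latent_log_tl)` (samples carry 5 ng of input DNA, so ALB
#' wells sit at the calibrator). Plate offsets are drawn per plate and target
#' with SD `plate_sd`; because the standard curve shares its plate's offset,
#' the offsets cancel in the downstream Pfaffl ratio and only curve-estimation
#' noise survives as a residual plate effect.
#'
#' @param latent Tibble with `subject_id` and `latent_log_tl`.
#' @param config A [cohort_config()] (supplies plate count, noise SDs and the
#'   true amplification efficiencies).
#' @param seed Integer seed.
#'
#' @return Tibble `subject_id, plate, well, target, replicate, ct, mass_ng`;
#'   standard wells have `subject_id == "STD"` and a non-missing `mass_ng`.
#' @export
simulate_ct_plates <- function(latent, config, seed = 1L) {
  set.seed(seed)
  n <- nrow(latent)
  n_plates <- config$n_plates
  plate <- rep_len(seq_len(n_plates), n)
  eff <- c(TEL = config$efficiency_tel, ALB = config$efficiency_alb)
  offsets <- matrix(stats::rnorm(n_plates * 2, 0, config$plate_sd),
                    nrow = n_plates, dimnames = list(NULL, c("TEL", "ALB")))

  sample_rows <- tidyr::expand_grid(
    idx = seq_len(n), target = c("TEL", "ALB"), replicate = 1:3
  )
  latent_contrib <- ifelse(sample_rows$target == "TEL",
                           latent$latent_log_tl[sample_rows$idx], 0)
  tcol_s <- ifelse(sample_rows$target == "TEL", 1L, 2L)
  sample_ct <- .ct_intercepts[sample_rows$target] +
    offsets[cbind(plate[sample_rows$idx], tcol_s)] -
    latent_contrib / log(eff[sample_rows$target]) +
    stats::rnorm(nrow(sample_rows), 0, config$ct_sd)
  samples <- tibble::tibble(
    subject_id = latent$subject_id[sample_rows$idx],
    plate = plate[sample_rows$idx],
    target = sample_rows$target,
    replicate = sample_rows$replicate,
    ct = unname(sample_ct),
    mass_ng = NA_real_
  )

  std_rows <- tidyr::expand_grid(
    plate = seq_len(n_plates), target = c("TEL", "ALB"),
    mass_ng = .standard_masses
  )
  tcol_z <- ifelse(std_rows$target == "TEL", 1L, 2L)
  std_ct <- .ct_intercepts[std_rows$target] +
    offsets[cbind(std_rows$plate, tcol_z)] -
    log(std_rows$mass_ng / 5) / log(eff[std_rows$target]) +
    stats::rnorm(nrow(std_rows), 0, config$ct_sd)
  standards <- tibble::tibble(
    subject_id = "STD",
    plate = std_rows$plate,
    target = std_rows$target,
    replicate = 1L,
    ct = unname(std_ct),
    mass_ng = std_rows$mass_ng
  )

  ct <- dplyr::bind_rows(samples, standards)
  ct <- ct[order(ct$plate, ct$subject_id, ct$target, ct$replicate), ]
  ct$well <- sprintf("P%02d.%03d", ct$plate,
                     stats::ave(ct$plate, ct$plate, FUN = seq_along))
  ct[c("subject_id", "plate", "well", "target", "replicate", "ct", "mass_ng")]
}

#' Simulate semen parameters
#'
#' Each parameter follows a first-moment model
#' `value = intercept + age_beta * age + beta_sperm_per_logTL * latent + noise`
#' truncated by clipping to its valid range (percentages to `[0, 100]`,
#' counts to non-negative). Parameters are generated independently: the joint
#' distribution of real semen profiles (e.g. total motility bounding
#' progressive motility) is deliberately not modelled.
#'
#' @param ages Numeric vector of ages in years.
#' @param smoker_flags Logical vector (kept as a covariate; smoking has no
#'   generative effect on the parameters in this model).
#' @param latent Numeric vector of latent log telomere ratios.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#'
#' @return Tibble with `subject_id` implicit by row order and one column per
#'   semen parameter.
#' @export
simulate_sperm <- function(ages, smoker_flags, latent, config, seed = 1L) {
  n <- length(ages)
  stopifnot(length(smoker_flags) == n, length(latent) == n)
  set.seed(seed)
  pars <- config$sperm_params
  out <- vector("list", nrow(pars))
  names(out) <- pars$parameter
  for (i in seq_len(nrow(pars))) {
    p <- pars$parameter[i]
    beta_age <- config$age_betas[[p]]
    intercept <- pars$mean[i] - beta_age * config$age_mean
    v <- intercept + beta_age * ages +
      config$beta_sperm_per_logTL * latent +
      stats::rnorm(n, 0, pars$sd[i])
    out[[p]] <- pmin(pmax(v, pars$lower[i]), pars$upper[i])
  }
  tibble::as_tibble(out)
}

#' Simulate a full cohort
#'
#' Composes [simulate_genotypes()], [simulate_latent_tl()],
#' [simulate_ct_plates()] and [simulate_sperm()] under per-stage sub-seeds
#' derived from `config$seed`, so the same configuration always yields the
#' identical cohort and each stage is reproducible on its own.
#'
#' @param config A [cohort_config()].
#' @param panel A [snp_panel()]; defaults to [default_tel_panel()].
#'
#' @return A list of class `tel_cohort` with elements `subjects` (id, age,
#'   smoker), `genotypes`, `latent` (the true log telomere ratios),
#'   `ct` (all qPCR wells) and `phenotypes` (age, smoking and the nine semen
#'   parameters), plus the `panel` and `config` used.
#' @export
simulate_cohort <- function(config = cohort_config(), panel = default_tel_panel()) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- validate_panel(panel)
  n <- config$n_subjects

  set.seed(derive_seed(config$seed, 1))
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  ages <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  smoker <- stats::runif(n) < config$smoking_prevalence
  subjects <- tibble::tibble(subject_id = subject_ids(n),
                             age = round(ages, 1), smoker = smoker)

  genotypes <- simulate_genotypes(panel, n, config$missing_rate,
                                  seed = derive_seed(config$seed, 2))
  latent <- simulate_latent_tl(genotypes, panel,
                               config$beta_tl_per_effect_allele,
                               config$sigma_tl,
                               seed = derive_seed(config$seed, 3))
  ct <- simulate_ct_plates(latent, config, seed = derive_seed(config$seed, 4))
  sperm <- simulate_sperm(subjects$age, subjects$smoker, latent$latent_log_tl,
                          config, seed = derive_seed(config$seed, 5))
  phenotypes <- dplyr::bind_cols(subjects, sperm)

  structure(list(subjects = subjects, genotypes = genotypes, latent = latent,
                 ct = ct, phenotypes = phenotypes, panel = panel,
                 config = config),
            class = "tel_cohort")
}

#' @export
print.tel_cohort <- function(x, ...) {
  cat("Synthetic telomere/semen cohort\n")
  cat(sprintf("  %d subjects, %d SNPs, %d qPCR plates\n",
              nrow(x$subjects), nrow(x$panel), x$config$n_plates))
  cat(sprintf("  seed %d; beta TL/allele %.3g; TL->sperm effect %.3g\n",
              x$config$seed, x$config$beta_tl_per_effect_allele,
              x$config$beta_sperm_per_logTL))
  invisible(x)
}

#' Write or read the cohort's delimited tables
#'
#' `write_cohort()` writes `genotypes.csv` (one column per rsID, calls as
#' `"X/Y"`, empty for missing), `ct.csv` (all qPCR wells; standard-curve wells
#' carry `mass_ng`) and `phenotypes.csv` into `dir`. The files are plain
#' comma-separated UTF-8 with a header row; two runs from the same cohort are
#' byte-identical.
#'
#' @param cohort A `tel_cohort`.
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` returns the three file paths invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tel_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.csv", "ct.csv", "phenotypes.csv"))
  readr::write_csv(cohort$genotypes, paths[1], na = "")
  readr::write_csv(cohort$ct, paths[2], na = "")
  readr::write_csv(cohort$phenotypes, paths[3], na = "")
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_genotypes <- function(path) {
  g <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_character()))
  g[g == ""] <- NA
  g
}

#' @rdname write_cohort
#' @param path File to read.
#' @export
read_ct <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), plate = readr::col_integer(),
    well = readr::col_character(), target = readr::col_character(),
    replicate = readr::col_integer(), ct = readr::col_double(),
    mass_ng = readr::col_double()))
}

#' @rdname write_cohort
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), smoker = readr::col_logical(),
    .default = readr::col_double()))
}
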