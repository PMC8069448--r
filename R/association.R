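#' Linear association model with age and smoking adjustment
#'
#' Ordinary least squares of `outcome` on `exposure` plus the adjustment set
#' (age in years, smoking yes/no), on complete cases. A numeric exposure
#' yields one record; a factor exposure yields one record per non-reference
#' level present in the data (its first level is the reference), which covers
#' both quintile exposures (2nd-5th vs 1st) and codominant genotype classes
#' (heterozygote and minor homozygote vs major homozygote, classes absent
#' from the sample collapsing away). Confidence intervals and p-values are
#' Wald-type from the t distribution.
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column (numeric or factor).
#' @param covariates Adjustment columns, default `c("age", "smoker")`; use
#'   `character(0)` for an unadjusted model.
#' @param min_n Minimum number of complete cases (default 10); below it the
#'   model is skipped with a message and an empty record set is returned.
#'
#' @return Tibble of association records: `outcome`, `exposure`, `term`,
#'   `n`, `coefficient`, `ci_low`, `ci_high`, `p_value`.
#' @export
fit_linear <- function(data, outcome, exposure,
                       covariates = c("age", "smoker"), min_n = 10) {
  y <- data[[outcome]]
  e <- data[[exposure]]
  if (is.null(y)) stop("no outcome column '", outcome, "'", call. = FALSE)
  if (is.null(e)) stop("no exposure column '", exposure, "'", call. = FALSE)
  cov_mat <- covariate_matrix(data, covariates)
  ok <- !is.na(y) & !is.na(e)
  if (length(covariates)) ok <- ok & stats::complete.cases(cov_mat)
  n <- sum(ok)
  if (n < min_n) {
    message("skipping ", outcome, " ~ ", exposure, ": only ", n,
            " complete cases")
    return(empty_records())
  }
  de <- design_exposure(e[ok], exposure)
  X <- cbind(`(Intercept)` = 1, de$cols, cov_mat[ok, , drop = FALSE])
  fit <- wald_ols(y[ok], X)
  idx <- 1 + seq_len(ncol(de$cols))
  new_records(outcome, exposure, de$terms, n,
              fit$coef[idx], fit$ci_low[idx], fit$ci_high[idx], fit$p[idx])
}

# Cheap tibble constructor for the model hot path.
new_records <- function(outcome, exposure, term, n, coefficient, ci_low,
                        ci_high, p_value) {
  k <- length(term)
  tibble::new_tibble(list(
    outcome = rep_len(outcome, k), exposure = rep_len(exposure, k),
    term = term, n = rep_len(as.integer(n), k),
    coefficient = unname(coefficient), ci_low = unname(ci_low),
    ci_high = unname(ci_high), p_value = unname(p_value)), nrow = k)
}

empty_records <- function() {
  tibble::tibble(outcome = character(), exposure = character(),
                 term = character(), n = integer(), coefficient = double(),
                 ci_low = double(), ci_high = double(), p_value = double())
}

covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("no covariate column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- vapply(covariates, function(cn) as.numeric(data[[cn]]),
              numeric(nrow(data)))
  m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, covariates))
  m
}

# Expand an exposure into design columns plus contrast labels.
design_exposure <- function(e, name) {
  if (is.factor(e) || is.character(e)) {
    e <- droplevels(factor(e))
    lv <- levels(e)
    if (length(lv) < 2) {
      stop("exposure '", name, "' has a single class in the analysis sample",
           call. = FALSE)
    }
    cols <- vapply(lv[-1], function(l) as.numeric(e == l), numeric(length(e)))
    cols <- matrix(cols, ncol = length(lv) - 1,
                   dimnames = list(NULL, lv[-1]))
    list(cols = cols, terms = paste(lv[-1], "vs", lv[1]))
  } else {
    if (stats::var(e) == 0) {
      stop("exposure '", name, "' is constant", call. = FALSE)
    }
    list(cols = matrix(e, ncol = 1, dimnames = list(NULL, name)),
         terms = "linear")
  }
}

# QR-based OLS with t-based Wald intervals; errors on rank deficiency.
wald_ols <- function(y, X) {
  qr_x <- qr(X)
  p <- ncol(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("collinear design; offending term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qr_x, y)
  res <- y - drop(X %*% coef)
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coef / se
  tq <- stats::qt(0.975, df)
  list(coef = coef, se = se, df = df,
       ci_low = coef - tq * se, ci_high = coef + tq * se,
       p = 2 * stats::pt(-abs(tval), df))
}

#' Linear model with a plate random intercept
#'
#' For models whose outcome is log telomere length, the reaction plate enters
#' as a random intercept: `outcome ~ exposure + covariates + (1 | plate)`,
#' fitted by REML via \pkg{lme4}. Fixed-effect inference is Wald-type on the
#' normal scale. When the estimated plate variance is zero the fit collapses
#' to the OLS solution; with a single plate the model falls back to OLS with
#' a warning.
#'
#' @inheritParams fit_linear
#' @param plate Name of the plate column, default `"plate"`.
#' @return Tibble of association records (same shape as [fit_linear()]).
#' @export
fit_plate_mixed <- function(data, outcome, exposure,
                            covariates = c("age", "smoker"),
                            plate = "plate", min_n = 10) {
  if (is.null(data[[plate]])) stop("no plate column '", plate, "'", call. = FALSE)
  keep <- !is.na(data[[outcome]]) & !is.na(data[[exposure]]) &
    !is.na(data[[plate]])
  for (cv in covariates) keep <- keep & !is.na(data[[cv]])
  d <- data[keep, c(outcome, exposure, covariates, plate)]
  n <- nrow(d)
  if (n < min_n) {
    message("skipping ", outcome, " ~ ", exposure, ": only ", n,
            " complete cases")
    return(empty_records())
  }
  if (length(unique(d[[plate]])) < 2) {
    warning("single plate in analysis sample; falling back to OLS")
    return(fit_linear(d, outcome, exposure, covariates, min_n))
  }
  de <- design_exposure(d[[exposure]], exposure)
  names(d)[names(d) == exposure] <- ".exposure"
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ .exposure + ",
    paste(c(covariates, paste0("(1 | `", plate, "`)")), collapse = " + ")))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  want <- if (is.numeric(d$.exposure)) ".exposure" else
    paste0(".exposure", levels(droplevels(factor(d$.exposure)))[-1])
  if (!all(want %in% names(fe))) {
    stop("collinear design; offending term(s): ",
         paste(setdiff(want, names(fe)), collapse = ", "), call. = FALSE)
  }
  est <- fe[want]
  ses <- se[match(want, names(fe))]
  z <- est / ses
  zq <- stats::qnorm(0.975)
  new_records(outcome, exposure, de$terms, n,
              est, est - zq * ses, est + zq * ses, 2 * stats::pnorm(-abs(z)))
}

#' Merge pipeline outputs into one analysis table
#'
#' Left-joins (on `subject_id`) the phenotype table with the telomere
#' quantification, teloscores, ABCD composites, additive dosages (columns
#' prefixed `dos_`) and codominant factors (prefixed `cod_`). Subjects
#' missing from a component (e.g. discarded by genotype QC, or without a
#' usable telomere measurement) keep their row with missing values and drop
#' per-model by complete-case analysis.
#'
#' @param phenotypes Phenotype tibble (`subject_id`, `age`, `smoker`, semen
#'   parameters).
#' @param stl Output of [quantify_stl()].
#' @param scores Output of [compute_teloscores()].
#' @param dosages Output of [encode_additive()].
#' @param codominant Output of [encode_codominant()].
#' @param abcd Output of [abcd_scores()].
#' @return One wide tibble keyed by `subject_id`.
#' @export
build_analysis_table <- function(phenotypes, stl, scores, dosages, codominant,
                                 abcd) {
  snps <- setdiff(names(dosages), "subject_id")
  dos <- stats::setNames(dosages, c("subject_id", paste0("dos_", snps)))
  cod <- stats::setNames(codominant,
                         c("subject_id", paste0("cod_",
                                                setdiff(names(codominant),
                                                        "subject_id"))))
  tab <- dplyr::left_join(
    phenotypes,
    stl[c("subject_id", "plate", "stl_ratio", "log_stl", "log_stl_residual")],
    by = "subject_id")
  tab <- dplyr::left_join(tab, scores, by = "subject_id")
  tab <- dplyr::left_join(tab, abcd[c("subject_id", "abcd_total", "abcd_mot")],
                          by = "subject_id")
  tab <- dplyr::left_join(tab, dos, by = "subject_id")
  dplyr::left_join(tab, cod, by = "subject_id")
}

sperm_outcomes <- function() {
  c(names(default_age_betas()), "abcd_total", "abcd_mot")
}

#' Run the full association scan
#'
#' Fits every exposure-outcome-model combination of the design:
#' \itemize{
#'   \item plate-residualized log STL (linear and in quintiles, 2nd-5th vs
#'     1st) against the nine semen parameters and the two ABCD composites;
#'   \item the scaled unweighted and weighted teloscores (linear and in
#'     quintiles) against the same outcomes, plus log STL as an outcome with
#'     a plate random intercept;
#'   \item every panel SNP under the additive coding (effect-allele dosage)
#'     and the codominant coding (genotype classes vs the major-allele
#'     homozygote) against the same outcomes, log STL again with the plate
#'     random effect.
#' }
#' All models adjust for age and smoking. Models with too few complete cases
#' or a single exposure class are skipped and recorded in the `skipped`
#' attribute; the scan always continues.
#'
#' @param analysis Analysis table from [build_analysis_table()].
#' @param panel The [snp_panel()] scanned.
#' @param alpha,m Passed to [apply_multiple_testing()].
#' @param covariates Adjustment set, default age and smoking status.
#' @return Tibble of association records with columns `outcome`, `exposure`,
#'   `form` (`linear`, `quintile`, `additive`, `codominant`), `term`, `n`,
#'   `coefficient`, `ci_low`, `ci_high`, `p_value`, `significant_nominal`,
#'   `significant_bonferroni`.
#' @export
run_scan <- function(analysis, panel, alpha = 0.05, m = 33,
                     covariates = c("age", "smoker")) {
  panel <- validate_panel(panel)
  tab <- analysis
  tab$stl_lin <- tab$log_stl_residual
  tab$stl_quint <- quint_factor(tab$log_stl_residual)
  tab$uw_lin <- tab$unweighted_scaled
  tab$uw_quint <- quint_factor(tab$unweighted_scaled)
  tab$w_lin <- tab$weighted_scaled
  tab$w_quint <- quint_factor(tab$weighted_scaled)

  acc <- list()
  skips <- character()
  add <- function(records, form, label) {
    if (nrow(records) == 0) {
      skips[[length(skips) + 1]] <<- label
    } else {
      records$form <- form
      acc[[length(acc) + 1]] <<- records
    }
  }
  try_fit <- function(fun, form, label, ...) {
    rec <- tryCatch(fun(...), error = function(e) {
      message("scan: ", label, " failed: ", conditionMessage(e))
      empty_records()
    })
    add(rec, form, label)
  }

  outs <- sperm_outcomes()
  for (out in outs) {
    try_fit(fit_linear, "linear", paste(out, "~ stl"),
            data = tab, outcome = out, exposure = "stl_lin",
            covariates = covariates)
    try_fit(fit_linear, "quintile", paste(out, "~ stl quintiles"),
            data = tab, outcome = out, exposure = "stl_quint",
            covariates = covariates)
  }
  score_cols <- c(teloscore_unweighted = "uw", teloscore_weighted = "w")
  for (sc in names(score_cols)) {
    stem <- score_cols[[sc]]
    for (out in outs) {
      try_fit(fit_linear, "linear", paste(out, "~", sc),
              data = tab, outcome = out, exposure = paste0(stem, "_lin"),
              covariates = covariates)
      try_fit(fit_linear, "quintile", paste(out, "~", sc, "quintiles"),
              data = tab, outcome = out, exposure = paste0(stem, "_quint"),
              covariates = covariates)
    }
    try_fit(fit_plate_mixed, "linear", paste("log_stl ~", sc),
            data = tab, outcome = "log_stl", exposure = paste0(stem, "_lin"),
            covariates = covariates)
    try_fit(fit_plate_mixed, "quintile", paste("log_stl ~", sc, "quintiles"),
            data = tab, outcome = "log_stl", exposure = paste0(stem, "_quint"),
            covariates = covariates)
  }
  for (snp in panel$snp_id) {
    for (out in outs) {
      try_fit(fit_linear, "additive", paste(out, "~", snp),
              data = tab, outcome = out, exposure = paste0("dos_", snp),
              covariates = covariates)
      try_fit(fit_linear, "codominant", paste(out, "~", snp, "codominant"),
              data = tab, outcome = out, exposure = paste0("cod_", snp),
              covariates = covariates)
    }
    try_fit(fit_plate_mixed, "additive", paste("log_stl ~", snp),
            data = tab, outcome = "log_stl", exposure = paste0("dos_", snp),
            covariates = covariates)
    try_fit(fit_plate_mixed, "codominant",
            paste("log_stl ~", snp, "codominant"),
            data = tab, outcome = "log_stl", exposure = paste0("cod_", snp),
            covariates = covariates)
  }

  records <- dplyr::bind_rows(acc)
  records$exposure <- clean_exposure_label(records$exposure)
  records <- records[c("outcome", "exposure", "form", "term", "n",
                       "coefficient", "ci_low", "ci_high", "p_value")]
  records <- apply_multiple_testing(records, alpha = alpha, m = m)
  attr(records, "skipped") <- unlist(skips)
  records
}

quint_factor <- function(v) {
  if (all(is.na(v))) return(factor(rep(NA_character_, length(v)),
                                   levels = paste0("Q", 1:5)))
  q <- suppressWarnings(quintile_categorize(v))
  factor(paste0("Q", q), levels = paste0("Q", 1:5))
}

clean_exposure_label <- function(x) {
  x <- sub("^dos_", "", x)
  x <- sub("^cod_", "", x)
  x[x %in% c("stl_lin", "stl_quint")] <- "stl"
  x[x %in% c("uw_lin", "uw_quint")] <- "teloscore_unweighted"
  x[x %in% c("w_lin", "w_quint")] <- "teloscore_weighted"
  x
}

#' Flag associations after multiple-testing correction
#'
#' The Bonferroni threshold `alpha / m` (default 0.05/33 = 0.0015 at two
#' significant figures, for 11 SNPs under three inheritance contrasts)
#' applies to the SNP records (`additive` and `codominant` forms); STL and
#' teloscore analyses are flagged at the nominal level only, and the
#' thresholds used are recorded as attributes.
#'
#' @param records Association record tibble with `p_value` and `form`.
#' @param alpha Nominal significance level.
#' @param m Number of tests behind the Bonferroni correction.
#' @return `records` with logical columns `significant_nominal` and
#'   `significant_bonferroni` (`NA` for non-SNP records), plus attributes
#'   `bonferroni_threshold` and `nominal_threshold`.
#' @export
apply_multiple_testing <- function(records, alpha = 0.05, m = 33) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  thr <- alpha / m
  is_snp <- records$form %in% c("additive", "codominant")
  records$significant_nominal <- records$p_value < alpha
  records$significant_bonferroni <- ifelse(is_snp, records$p_value < thr, NA)
  attr(records, "bonferroni_threshold") <- thr
  attr(records, "nominal_threshold") <- alpha
  records
}

#' One-call analysis of a cohort
#'
#' Runs the complete pipeline on a simulated (or equivalently structured)
#' cohort: genotype QC and call-rate filtering, dosage and codominant
#' encodings, teloscores, qPCR quantification of relative telomere length,
#' ABCD composites, and the association scan.
#'
#' @param cohort A `tel_cohort` from [simulate_cohort()], or a list with
#'   elements `genotypes`, `ct`, `phenotypes` (and optionally `panel`).
#' @param panel SNP panel; defaults to the cohort's own.
#' @param centiles ABCD reference centiles.
#' @param qc_rule,qc_threshold Triplicate QC settings for [quantify_stl()].
#' @param call_rate_threshold Subject call-rate cut for genotype QC.
#' @param alpha,m Multiple-testing settings for the scan.
#' @return List with `records` (the scan results), `analysis` (the merged
#'   table), and the intermediate `qc`, `stl`, `scores`, `abcd` objects.
#' @export
analyze_cohort <- function(cohort, panel = NULL,
                           centiles = who2010_centiles(),
                           qc_rule = "cv", qc_threshold = 0.05,
                           call_rate_threshold = 0.80,
                           alpha = 0.05, m = 33) {
  if (is.null(panel)) panel <- cohort$panel
  panel <- validate_panel(panel)
  qc <- genotype_qc(cohort$genotypes, panel, call_rate_threshold)
  dosages <- encode_additive(qc$kept, panel)
  codominant <- encode_codominant(qc$kept, panel)
  scores <- compute_teloscores(dosages, panel)
  stl <- quantify_stl(cohort$ct, rule = qc_rule, threshold = qc_threshold)
  abcd <- abcd_scores(cohort$phenotypes, centiles)
  analysis <- build_analysis_table(cohort$phenotypes, stl, scores, dosages,
                                   codominant, abcd)
  records <- run_scan(analysis, panel, alpha = alpha, m = m)
  list(records = records, analysis = analysis, qc = qc, stl = stl,
       scores = scores, abcd = abcd)
}
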