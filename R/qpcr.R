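#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(input mass) over a dilution series. The
#' amplification efficiency is recovered from the slope as
#' `E = 10^(-1/slope)` (perfect doubling gives a slope of -1/log10(2), about
#' -3.32, hence E = 2). The calibrator Ct -- the fitted Ct at 5 ng of input --
#' is returned with the curve and anchors the Pfaffl ratio.
#'
#' @param mass_ng Input DNA masses in ng, all positive, at least 3 distinct.
#' @param ct Observed Ct values (cycles), same length.
#' @param plate,target Optional labels carried on the fit.
#' @param calibrator_mass_ng Input mass defining the calibrator (default 5).
#'
#' @return An object of class `standard_curve`: `slope` (cycles per log10 ng),
#'   `intercept`, `efficiency`, `r_squared`, `calibrator_ct`, `n_points`.
#' @export
#' @examples
#' masses <- 20 * 0.5^(0:6)
#' fit_standard_curve(masses, 30 - log(masses / 5) / log(2))$efficiency
fit_standard_curve <- function(mass_ng, ct, plate = NA, target = NA,
                               calibrator_mass_ng = 5) {
  if (length(mass_ng) != length(ct)) stop("mass and ct lengths differ", call. = FALSE)
  keep <- is.finite(mass_ng) & is.finite(ct)
  mass_ng <- mass_ng[keep]; ct <- ct[keep]
  if (any(mass_ng <= 0)) stop("standard-curve masses must be positive", call. = FALSE)
  if (length(unique(mass_ng)) < 3) {
    stop("standard curve needs at least 3 distinct dilution points", call. = FALSE)
  }
  x <- log10(mass_ng)
  xc <- x - mean(x); yc <- ct - mean(ct)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  intercept <- mean(ct) - slope * mean(x)
  r2 <- if (sum(yc^2) == 0) 1 else sum(xc * yc)^2 / (sxx * sum(yc^2))
  if (slope >= 0) {
    stop("standard-curve slope is non-negative; Ct must fall with input mass",
         call. = FALSE)
  }
  efficiency <- 10^(-1 / slope)
  structure(list(
    plate = plate, target = target,
    slope = slope, intercept = intercept,
    efficiency = efficiency, r_squared = r2,
    calibrator_ct = intercept + slope * log10(calibrator_mass_ng),
    calibrator_mass_ng = calibrator_mass_ng,
    n_points = length(ct)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve (%s, plate %s): slope %.4f, E = %.4f, R2 = %.4f\n",
    x$target, x$plate, x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Predicted Ct at a given input mass
#' @param curve A `standard_curve`.
#' @param mass_ng Input mass in ng.
#' @return Predicted Ct (cycles).
#' @export
predict_ct <- function(curve, mass_ng) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * log10(mass_ng)
}

#' Triplicate quality control
#'
#' Two discard rules are available. `"literal"` removes any well whose Ct
#' deviates from the triplicate mean by more than `threshold` (default 5%) of
#' the triplicate's standard deviation, then re-averages the survivors. Note
#' that this rule is extremely stringent: unless the wells are nearly
#' identical, every well of a 3-point set deviates by more than 0.05 SD, so
#' the whole set is discarded. `"cv"` treats the threshold as a coefficient of
#' variation (SD/mean, default 5%): a set whose CV exceeds it loses its most
#' deviant well and is re-checked; if the CV still exceeds the threshold with
#' two wells left the set is unusable. A set reduced below 2 survivors is
#' always flagged unusable. SDs use the sample (n-1) denominator.
#'
#' @param cts Numeric vector of 1-3 (or more) Ct values from one
#'   plate/target.
#' @param rule `"literal"` or `"cv"`.
#' @param threshold Discard threshold; defaults to 0.05 under either rule.
#'
#' @return List with `kept` (surviving Ct values), `mean_ct`, `flags`
#'   (logical, `TRUE` where the well was kept) and `usable`.
#' @export
#' @examples
#' qc_triplicates(c(20, 20, 20))
#' qc_triplicates(c(20.0, 20.1, 23.0), rule = "cv")
qc_triplicates <- function(cts, rule = c("literal", "cv"), threshold = 0.05) {
  rule <- match.arg(rule)
  if (length(cts) == 0 || !any(is.finite(cts))) {
    stop("triplicate QC needs at least one finite Ct", call. = FALSE)
  }
  m <- matrix(NA_real_, 1, length(cts))
  m[1, ] <- cts
  res <- qc_ct_matrix(m, rule, threshold)
  flags <- res$keep[1, ]
  flags[!is.finite(cts)] <- FALSE
  list(kept = cts[which(flags)], mean_ct = res$mean_ct[1],
       flags = flags, usable = res$usable[1])
}

# Vectorized triplicate QC over a groups x replicates matrix (NA-padded).
qc_ct_matrix <- function(m, rule, threshold = 0.05) {
  k <- rowSums(!is.na(m))
  rm <- rowMeans(m, na.rm = TRUE)
  dev <- abs(m - rm)
  rsd <- sqrt(rowSums(dev^2, na.rm = TRUE) / pmax(k - 1, 1))
  if (rule == "literal") {
    keep <- dev <= threshold * rsd
    keep[is.na(keep)] <- FALSE
  } else {
    keep <- !is.na(m)
    cv <- rsd / abs(rm)
    bad <- is.finite(cv) & cv > threshold & k > 2
    while (any(bad)) {
      worst <- max.col(replace(dev, !keep | is.na(dev), -Inf), ties.method = "first")
      keep[cbind(which(bad), worst[bad])] <- FALSE
      mk <- m
      mk[!keep] <- NA
      k <- rowSums(keep)
      rm <- rowMeans(mk, na.rm = TRUE)
      dev <- abs(mk - rm)
      rsd <- sqrt(rowSums(dev^2, na.rm = TRUE) / pmax(k - 1, 1))
      cv <- rsd / abs(rm)
      bad <- is.finite(cv) & cv > threshold & k > 2
    }
  }
  mk <- m
  mk[!keep] <- NA
  n_kept <- rowSums(keep)
  mean_ct <- rowMeans(mk, na.rm = TRUE)
  mean_ct[n_kept == 0] <- NA_real_
  usable <- n_kept >= 2
  if (rule == "cv") {
    cv_final <- sqrt(rowSums((mk - rowMeans(mk, na.rm = TRUE))^2, na.rm = TRUE) /
                       pmax(n_kept - 1, 1)) / abs(mean_ct)
    usable <- usable & (!is.finite(cv_final) | cv_final <= threshold)
  }
  list(keep = keep, mean_ct = mean_ct, n_kept = n_kept, usable = usable)
}

#' Pfaffl efficiency-corrected relative telomere length
#'
#' The relative telomere length of a sample is
#' `E_tel^(Ct_cal,tel - Ct_tel) / E_alb^(Ct_cal,alb - Ct_alb)`, where each
#' calibrator Ct is the standard curve's fitted Ct at the calibrator input
#' (5 ng) on the sample's plate and each efficiency comes from the same
#' curve. With both efficiencies equal to 2 this reduces to the familiar
#' `2^(dCt_tel - dCt_alb)` double-delta-Ct form.
#'
#' @param mean_ct_tel,mean_ct_alb QC'd mean Cts of the sample (vectors allowed).
#' @param curve_tel,curve_alb `standard_curve` fits for the two targets from
#'   the sample's plate.
#'
#' @return Numeric vector of telomere/albumin ratios.
#' @export
pfaffl_ratio <- function(mean_ct_tel, mean_ct_alb, curve_tel, curve_alb) {
  stopifnot(inherits(curve_tel, "standard_curve"),
            inherits(curve_alb, "standard_curve"))
  if (!is.na(curve_tel$plate) && !is.na(curve_alb$plate) &&
      !identical(curve_tel$plate, curve_alb$plate)) {
    stop("telomere and albumin curves come from different plates", call. = FALSE)
  }
  for (e in c(curve_tel$efficiency, curve_alb$efficiency)) {
    if (e <= 1 || e >= 4) {
      stop("amplification efficiency ", format(e), " outside sanity band (1, 4)",
           call. = FALSE)
    }
  }
  curve_tel$efficiency^(curve_tel$calibrator_ct - mean_ct_tel) /
    curve_alb$efficiency^(curve_alb$calibrator_ct - mean_ct_alb)
}

#' Centre log telomere values on their plate
#'
#' Subtracts each plate's mean, which equals taking residuals from an OLS
#' regression of log STL on plate indicators. The residuals sum to zero
#' within every plate and are the exposure used whenever STL enters a model
#' as an independent variable.
#'
#' @param log_stl Numeric vector.
#' @param plate Plate identifier per value.
#' @return Numeric vector of plate-centred values (NA preserved).
#' @export
residualize_on_plate <- function(log_stl, plate) {
  stopifnot(length(log_stl) == length(plate))
  means <- stats::ave(log_stl, plate, FUN = function(v) mean(v, na.rm = TRUE))
  log_stl - means
}

#' Quantify relative sperm telomere length from a Ct table
#'
#' End-to-end quantification: fits per-plate standard curves for both targets
#' from the standard wells (rows with a non-missing `mass_ng`), applies
#' triplicate QC to every sample's TEL and ALB wells, forms the Pfaffl ratio
#' against the 5 ng calibrator of the sample's plate, log-transforms it and
#' plate-centres the result. The pipeline default QC rule is `"cv"`; the
#' `"literal"` rule is available but discards nearly all noisy triplicates
#' (see [qc_triplicates()]).
#'
#' @param ct A Ct table as produced by [simulate_ct_plates()] or
#'   [read_ct()]: columns `subject_id, plate, target, replicate, ct, mass_ng`.
#' @param rule,threshold Triplicate QC rule, see [qc_triplicates()].
#' @param curves `"per_plate"` (default) fits one curve per plate and target;
#'   `"pooled"` fits a single curve per target from all plates' standard
#'   wells, for runs whose plates lack their own dilution series.
#'
#' @return Tibble with one row per subject: `subject_id, plate, mean_ct_tel,
#'   mean_ct_alb, n_kept_tel, n_kept_alb, stl_ratio, log_stl,
#'   log_stl_residual, usable`. Subjects failing QC keep their row with
#'   missing ratio columns.
#' @export
quantify_stl <- function(ct, rule = c("cv", "literal"), threshold = 0.05,
                         curves = c("per_plate", "pooled")) {
  rule <- match.arg(rule)
  curves <- match.arg(curves)
  needed <- c("subject_id", "plate", "target", "replicate", "ct", "mass_ng")
  stopifnot(all(needed %in% names(ct)))

  std <- ct[!is.na(ct$mass_ng), ]
  if (nrow(std) == 0) stop("no standard-curve wells (mass_ng) found", call. = FALSE)
  smp <- ct[is.na(ct$mass_ng) & ct$subject_id != "STD", ]

  plates <- sort(unique(smp$plate))
  fit_for <- function(pl, tg) {
    rows <- if (curves == "pooled") std$target == tg else
      std$target == tg & std$plate == pl
    if (!any(rows)) {
      stop("no ", tg, " standard curve for plate ", pl, call. = FALSE)
    }
    fit_standard_curve(std$mass_ng[rows], std$ct[rows],
                       plate = if (curves == "pooled") NA else pl, target = tg)
  }
  curve_tab <- list(
    TEL = lapply(plates, fit_for, tg = "TEL"),
    ALB = lapply(plates, fit_for, tg = "ALB")
  )

  key <- paste(smp$subject_id, smp$plate, smp$target, sep = "\r")
  ukey <- unique(key)
  gidx <- match(key, ukey)
  rep_within <- stats::ave(seq_along(gidx), gidx, FUN = seq_along)
  mat <- matrix(NA_real_, length(ukey), max(rep_within))
  mat[cbind(gidx, rep_within)] <- smp$ct
  qc <- qc_ct_matrix(mat, rule, threshold)

  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  gtab <- tibble::tibble(subject_id = parts[, 1],
                         plate = as.integer(parts[, 2]),
                         target = parts[, 3],
                         mean_ct = qc$mean_ct, n_kept = qc$n_kept,
                         ok = qc$usable)
  wide <- tidyr::pivot_wider(gtab, names_from = "target",
                             values_from = c("mean_ct", "n_kept", "ok"))
  for (col in c("mean_ct_TEL", "mean_ct_ALB", "n_kept_TEL", "n_kept_ALB")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  pl_i <- match(wide$plate, plates)
  e_tel <- vapply(curve_tab$TEL, `[[`, numeric(1), "efficiency")[pl_i]
  e_alb <- vapply(curve_tab$ALB, `[[`, numeric(1), "efficiency")[pl_i]
  cal_tel <- vapply(curve_tab$TEL, `[[`, numeric(1), "calibrator_ct")[pl_i]
  cal_alb <- vapply(curve_tab$ALB, `[[`, numeric(1), "calibrator_ct")[pl_i]

  usable <- !is.na(wide$ok_TEL) & wide$ok_TEL &
    !is.na(wide$ok_ALB) & wide$ok_ALB
  ratio <- e_tel^(cal_tel - wide$mean_ct_TEL) /
    e_alb^(cal_alb - wide$mean_ct_ALB)
  ratio[!usable] <- NA_real_
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    plate = wide$plate,
    mean_ct_tel = wide$mean_ct_TEL,
    mean_ct_alb = wide$mean_ct_ALB,
    n_kept_tel = wide$n_kept_TEL,
    n_kept_alb = wide$n_kept_ALB,
    stl_ratio = ratio,
    log_stl = log(ratio),
    usable = usable
  )
  out$log_stl_residual <- residualize_on_plate(out$log_stl, out$plate)
  out[order(out$subject_id), ]
}
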