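#' Reference percentiles for the ABCD bands
#'
#' Default 5th/50th/95th reference centiles for the four banded semen
#' parameters, taken from the WHO 2010 semen-analysis reference distribution
#' (fertile men): sperm concentration (10^6/mL), progressive motility (%),
#' total motility (%) and normal morphology (%). The table is a configuration
#' object: replace any row to band against cohort-empirical or updated
#' reference percentiles.
#'
#' @return Tibble with columns `parameter`, `p5`, `p50`, `p95`.
#' @export
who2010_centiles <- function() {
  tibble::tibble(
    parameter = c("concentration", "progressive_motility", "total_motility",
                  "normal_morphology"),
    p5 = c(15, 32, 40, 4),
    p50 = c(73, 55, 61, 15),
    p95 = c(213, 72, 78, 44)
  )
}

validate_centiles <- function(p5, p50, p95) {
  if (!(is.finite(p5) && is.finite(p50) && is.finite(p95)) ||
      !(p5 < p50 && p50 < p95)) {
    stop("centiles must satisfy p5 < p50 < p95", call. = FALSE)
  }
  invisible(TRUE)
}

#' ABCD category of a semen parameter
#'
#' Bands a value against reference percentiles: A below the 5th percentile,
#' B from the 5th up to the 50th, C from the 50th up to the 95th, D at or
#' above the 95th. Bands B and C are half-open (`[p5, p50)`, `[p50, p95)`),
#' so a value exactly at a reference percentile falls in the upper band; A is
#' strictly below p5. Higher bands mean higher parameter values, i.e. better
#' semen quality for these four parameters.
#'
#' @param value Numeric vector of parameter values.
#' @param p5,p50,p95 Reference percentiles, `p5 < p50 < p95`.
#' @return Character vector of categories `"A"`, `"B"`, `"C"`, `"D"` (`NA`
#'   for missing values).
#' @export
#' @examples
#' abcd_category(c(10, 32, 60, 80), p5 = 32, p50 = 55, p95 = 72)
abcd_category <- function(value, p5, p50, p95) {
  validate_centiles(p5, p50, p95)
  out <- rep(NA_character_, length(value))
  ok <- is.finite(value)
  out[ok & value < p5] <- "A"
  out[ok & value >= p5 & value < p50] <- "B"
  out[ok & value >= p50 & value < p95] <- "C"
  out[ok & value >= p95] <- "D"
  out
}

#' Pseudo-continuous ABCD value
#'
#' Converts a banded parameter into a number usable by linear models. The
#' default `"integer"` mode assigns 1/2/3/4 to bands A/B/C/D. The
#' `"interpolated"` mode adds the value's linear position inside its band, so
#' e.g. the middle of band B maps to 2.5; band A interpolates from 0 to p5
#' (values below 0 clamp to 1) and band D uses the C-band width as its scale,
#' capped below 5. Both modes are bounded in `[1, 5)` and the interpolated
#' value always floors to the integer code.
#'
#' @inheritParams abcd_category
#' @param mode `"integer"` or `"interpolated"`.
#' @return Numeric vector in `[1, 5)`.
#' @export
abcd_pseudo_continuous <- function(value, p5, p50, p95,
                                   mode = c("integer", "interpolated")) {
  mode <- match.arg(mode)
  cat <- abcd_category(value, p5, p50, p95)
  base <- c(A = 1, B = 2, C = 3, D = 4)[cat]
  if (mode == "integer") return(unname(base))
  frac <- rep(NA_real_, length(value))
  ok <- !is.na(cat)
  frac[ok & cat == "A"] <- pmax(value[ok & cat == "A"], 0) / p5
  frac[ok & cat == "B"] <- (value[ok & cat == "B"] - p5) / (p50 - p5)
  frac[ok & cat == "C"] <- (value[ok & cat == "C"] - p50) / (p95 - p50)
  frac[ok & cat == "D"] <- (value[ok & cat == "D"] - p95) / (p95 - p50)
  unname(base + pmin(pmax(frac, 0), 1 - 1e-9))
}

#' ABCD composite semen-quality scores
#'
#' Bands the four reference parameters (sperm concentration, progressive
#' motility, total motility, normal morphology) of every subject, converts
#' each band to its pseudo-continuous value, and sums: the total ABCD score
#' over all four (range 4-16 in integer mode) and the motility-only
#' ABCD_mot over progressive plus total motility (range 2-8). A subject
#' missing any required parameter gets a missing composite.
#'
#' @param phenotypes Phenotype tibble containing `subject_id` and the four
#'   parameter columns named as in [who2010_centiles()].
#' @param centiles Reference centile table, default [who2010_centiles()].
#' @param mode Pseudo-continuous mode, see [abcd_pseudo_continuous()].
#' @return Tibble: `subject_id`, per-parameter `cat_*` and `val_*` columns,
#'   `abcd_total`, `abcd_mot`, and the `mode` used.
#' @export
abcd_scores <- function(phenotypes, centiles = who2010_centiles(),
                        mode = c("integer", "interpolated")) {
  mode <- match.arg(mode)
  missing_par <- setdiff(centiles$parameter, names(phenotypes))
  if (length(missing_par) > 0) {
    stop("phenotypes lack parameters: ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(subject_id = phenotypes$subject_id)
  vals <- matrix(NA_real_, nrow(phenotypes), nrow(centiles))
  for (i in seq_len(nrow(centiles))) {
    p <- centiles$parameter[i]
    x <- phenotypes[[p]]
    out[[paste0("cat_", p)]] <-
      abcd_category(x, centiles$p5[i], centiles$p50[i], centiles$p95[i])
    vals[, i] <- abcd_pseudo_continuous(x, centiles$p5[i], centiles$p50[i],
                                        centiles$p95[i], mode)
    out[[paste0("val_", p)]] <- vals[, i]
  }
  mot <- match(c("progressive_motility", "total_motility"), centiles$parameter)
  out$abcd_total <- rowSums(vals)              # NA if any parameter missing
  out$abcd_mot <- rowSums(vals[, mot, drop = FALSE])
  out$mode <- mode
  out
}
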