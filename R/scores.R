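#' Telomere genetic scores
#'
#' The unweighted score of a subject is the sum of its effect-allele dosages
#' over the panel (0 to 22 on an 11-SNP panel: 0 = fewest long-telomere
#' alleles, 22 = most). The weighted score multiplies each dosage by the
#' SNP's literature effect size before summing; weights come from published
#' GWAS estimates rather than being re-fit, to avoid overfitting. Missing
#' dosages are skipped by the raw sums; the scaled variants divide by the
#' number of genotyped SNPs and multiply by the panel size so that subjects
#' with partial genotyping get comparable values (raw and scaled coincide for
#' fully genotyped subjects).
#'
#' @param dosages Dosage tibble from [encode_additive()] (`subject_id` plus
#'   0/1/2 columns per SNP) or a bare numeric matrix/vector of dosages.
#' @param panel The matching [snp_panel()]; supplies the weights.
#'
#' @return `compute_teloscores()` returns a tibble: `subject_id`,
#'   `n_genotyped`, `unweighted_raw`, `weighted_raw`, `unweighted_scaled`,
#'   `weighted_scaled`. Subjects with no genotyped SNP get `NA` scores.
#' @export
compute_teloscores <- function(dosages, panel) {
  panel <- validate_panel(panel)
  dmat <- as.matrix(dosages[panel$snp_id])
  n_genotyped <- rowSums(!is.na(dmat))
  uw <- unweighted_score(dmat)
  w <- weighted_score(dmat, stats::setNames(panel$weight, panel$snp_id))
  tibble::tibble(
    subject_id = dosages$subject_id,
    n_genotyped = n_genotyped,
    unweighted_raw = uw,
    weighted_raw = w,
    unweighted_scaled = scaled_score(uw, n_genotyped, nrow(panel)),
    weighted_scaled = scaled_score(w, n_genotyped, nrow(panel))
  )
}

#' @rdname compute_teloscores
#' @export
unweighted_score <- function(dosages) {
  dmat <- dosage_matrix(dosages)
  s <- rowSums(dmat, na.rm = TRUE)
  s[rowSums(!is.na(dmat)) == 0] <- NA_real_
  s
}

#' @rdname compute_teloscores
#' @param weights Named (or positionally matching) numeric vector of
#'   per-allele weights, one per SNP column.
#' @export
weighted_score <- function(dosages, weights) {
  dmat <- dosage_matrix(dosages)
  if (!is.null(names(weights)) && !is.null(colnames(dmat))) {
    if (!all(colnames(dmat) %in% names(weights))) {
      stop("panel weights missing for: ",
           paste(setdiff(colnames(dmat), names(weights)), collapse = ", "),
           call. = FALSE)
    }
    weights <- weights[colnames(dmat)]
  }
  if (length(weights) != ncol(dmat)) {
    stop("one weight per SNP is required", call. = FALSE)
  }
  if (anyNA(weights)) stop("weights must not be missing", call. = FALSE)
  wmat <- sweep(dmat, 2, weights, `*`)
  s <- rowSums(wmat, na.rm = TRUE)
  s[rowSums(!is.na(dmat)) == 0] <- NA_real_
  s
}

#' @rdname compute_teloscores
#' @param raw Raw (unweighted or weighted) score values.
#' @param n_genotyped Number of non-missing SNPs behind each raw score.
#' @param panel_size Full panel size, default 11.
#' @export
scaled_score <- function(raw, n_genotyped, panel_size = 11) {
  if (any(n_genotyped > panel_size, na.rm = TRUE)) {
    stop("n_genotyped cannot exceed panel_size", call. = FALSE)
  }
  out <- raw / n_genotyped * panel_size
  out[!is.na(n_genotyped) & n_genotyped == 0] <- NA_real_
  out
}

dosage_matrix <- function(dosages) {
  if (is.data.frame(dosages)) {
    dosages <- as.matrix(dosages[setdiff(names(dosages), "subject_id")])
  }
  if (is.vector(dosages)) dosages <- matrix(dosages, nrow = 1)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  dosages
}

#' Quintile categorization of a continuous exposure
#'
#' Rank-based fifths: cut points sit at the 20/40/60/80th sample percentiles,
#' category 1 is the lowest fifth (the reference group in regression models).
#' Ties share the lower category (minimum-rank convention), so the category
#' counts are equal up to one subject except where ties straddle a boundary.
#'
#' @param values Numeric vector; `NA` propagates.
#' @return Integer vector of categories 1-5.
#' @export
#' @examples
#' table(quintile_categorize(1:100))
quintile_categorize <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  ok <- !is.na(values)
  n <- sum(ok)
  out <- rep(NA_integer_, length(values))
  if (n == 0) return(out)
  if (length(unique(values[ok])) < 5) {
    warning("fewer than 5 distinct values; quintiles are degenerate")
  }
  r <- rank(values[ok], ties.method = "min")
  out[ok] <- pmin(5L, as.integer(ceiling(r * 5 / n)))
  out
}
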