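#' Define a telomere-length SNP panel
#'
#' A panel is the single source of truth for how genotypes are turned into
#' effect-allele dosages and genetic scores: it records, for each SNP, the
#' major and minor allele, which allele is associated with longer telomeres
#' (the effect allele), the per-allele literature weight used by the weighted
#' score, and the minor-allele frequency used only by the cohort simulator.
#'
#' @param snp_id Character vector of rsIDs.
#' @param gene Gene label for each SNP.
#' @param major_allele,minor_allele Single-nucleotide alleles.
#' @param effect_allele Allele associated with longer telomere length; must be
#'   the major or the minor allele of the same SNP.
#' @param weight Per-allele effect size on telomere length, in the units of the
#'   literature source (used only for the weighted score, so the unit cancels
#'   in downstream standardized analyses).
#' @param maf Minor-allele frequency in `(0, 0.5]`; used by
#'   [simulate_genotypes()].
#'
#' @return A tibble of class `snp_panel` with one row per SNP.
#' @seealso [default_tel_panel()] for the 11-SNP telomere panel shipped with
#'   the package.
#' @export
#' @examples
#' snp_panel("rs0001", "GENE", "C", "A", "A", weight = 0.1, maf = 0.2)
snp_panel <- function(snp_id, gene, major_allele, minor_allele, effect_allele,
                      weight, maf) {
  panel <- tibble::tibble(
    snp_id = as.character(snp_id),
    gene = as.character(gene),
    major_allele = toupper(as.character(major_allele)),
    minor_allele = toupper(as.character(minor_allele)),
    effect_allele = toupper(as.character(effect_allele)),
    weight = as.numeric(weight),
    maf = as.numeric(maf)
  )
  validate_panel(panel)
}

#' @rdname snp_panel
#' @param panel A data frame with the `snp_panel` columns.
#' @export
validate_panel <- function(panel) {
  required <- c("snp_id", "gene", "major_allele", "minor_allele",
                "effect_allele", "weight", "maf")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) == 0) stop("panel must contain at least one SNP", call. = FALSE)
  if (anyDuplicated(panel$snp_id)) stop("duplicated snp_id in panel", call. = FALSE)
  nucs <- c("A", "C", "G", "T")
  if (!all(panel$major_allele %in% nucs) || !all(panel$minor_allele %in% nucs)) {
    stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  }
  if (any(panel$major_allele == panel$minor_allele)) {
    stop("major and minor allele must differ", call. = FALSE)
  }
  ok_effect <- panel$effect_allele == panel$major_allele |
    panel$effect_allele == panel$minor_allele
  if (!all(ok_effect)) {
    stop("effect_allele must be the major or minor allele (",
         paste(panel$snp_id[!ok_effect], collapse = ", "), ")", call. = FALSE)
  }
  if (!all(is.finite(panel$weight))) stop("weights must be finite", call. = FALSE)
  if (!all(panel$maf > 0 & panel$maf <= 0.5)) {
    stop("maf must be in (0, 0.5]", call. = FALSE)
  }
  class(panel) <- c("snp_panel", class(tibble::tibble()))
  panel
}

#' The 11-SNP telomere-length panel
#'
#' Eleven SNPs reported by genome-wide association studies of leukocyte
#' telomere length, commonly combined into a telomere genetic score
#' ("teloscore"). Effect alleles, weights and European minor-allele
#' frequencies shipped here are defaults assembled from the cited GWAS
#' literature; they are configurable, not hard-coded in any scoring logic,
#' and should be replaced by the user's preferred source when it differs.
#' Weights are per-allele effects on leukocyte telomere length (kb-scale
#' units as published).
#'
#' @return A `snp_panel` tibble with 11 rows.
#' @export
#' @examples
#' default_tel_panel()
default_tel_panel <- function() {
  snp_panel(
    snp_id = c("rs11125529", "rs6772228", "rs10936599", "rs7675998",
               "rs2736100", "rs9420907", "rs3027234", "rs8105767",
               "rs412658", "rs6028466", "rs755017"),
    gene = c("ACYP2", "PXK", "TERC", "NAF1", "TERT", "OBFC1", "CTC1",
             "ZNF208", "ZNF676", "DHX35", "ZBTB46"),
    major_allele = c("C", "T", "C", "G", "C", "C", "C", "A", "C", "G", "A"),
    minor_allele = c("A", "A", "T", "A", "A", "A", "T", "G", "T", "A", "G"),
    # allele associated with longer telomeres, per the GWAS reports
    effect_allele = c("A", "T", "C", "G", "A", "C", "C", "G", "C", "G", "G"),
    weight = c(0.056, 0.037, 0.117, 0.048, 0.078, 0.069, 0.042, 0.048,
               0.055, 0.058, 0.062),
    maf = c(0.14, 0.06, 0.25, 0.22, 0.49, 0.13, 0.23, 0.30, 0.35, 0.05, 0.13)
  )
}

# Frequency of the effect allele implied by the panel MAF.
effect_allele_freq <- function(panel) {
  ifelse(panel$effect_allele == panel$minor_allele, panel$maf, 1 - panel$maf)
}
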