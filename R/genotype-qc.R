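#' Per-subject and per-SNP genotype call rates
#'
#' @param genotypes Genotype tibble: `subject_id` plus one call column per
#'   SNP (`"X/Y"` strings, `NA` for missing).
#' @return A list with tibbles `subject` (`subject_id`, `call_rate`) and
#'   `snp` (`snp_id`, `call_rate`).
#' @export
call_rates <- function(genotypes) {
  calls <- as.matrix(genotypes[setdiff(names(genotypes), "subject_id")])
  if (length(calls) == 0) stop("genotype table has no SNP columns", call. = FALSE)
  ok <- !is.na(calls) & calls != ""
  list(
    subject = tibble::tibble(subject_id = genotypes$subject_id,
                             call_rate = rowMeans(ok)),
    snp = tibble::tibble(snp_id = colnames(calls), call_rate = colMeans(ok))
  )
}

#' Filter subjects on genotype call rate
#'
#' A subject is kept when the fraction of non-missing SNP calls is at least
#' `threshold`; a strictly lower call rate discards, so a subject at exactly
#' the threshold survives. The conventional cut of 80% corresponds to about
#' 9 genotyped SNPs of an 11-SNP panel.
#'
#' @param genotypes Genotype tibble.
#' @param threshold Minimum call rate in `(0, 1]`, default 0.80.
#' @return List with `kept` (filtered tibble), `discarded` (subject ids) and
#'   `call_rate` (named numeric, all subjects).
#' @export
subject_call_rate_filter <- function(genotypes, threshold = 0.80) {
  if (nrow(genotypes) == 0) stop("empty genotype table", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  cr <- call_rates(genotypes)$subject
  keep <- cr$call_rate >= threshold
  list(kept = genotypes[keep, ],
       discarded = genotypes$subject_id[!keep],
       call_rate = stats::setNames(cr$call_rate, cr$subject_id))
}

#' Hardy-Weinberg equilibrium test
#'
#' Compares observed genotype counts to the Hardy-Weinberg expectations
#' computed from the observed allele frequency. The default is the 1-df
#' chi-square goodness-of-fit test, the standard choice at cohort scale with
#' common alleles; `method = "exact"` gives the exact conditional test
#' (summing the probabilities of all heterozygote counts no more probable
#' than the observed one), preferable for rare alleles. A monomorphic SNP has
#' no defined test and returns `NA`.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts (vectors allowed for
#'   the chi-square method).
#' @param method `"chisq"` or `"exact"`.
#' @return Tibble with columns `chi2` (NA for the exact test), `p_value` and
#'   `method`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)        # perfect HWE: chi2 = 0, p = 1
#' hwe_test(50, 0, 50)         # total heterozygote deficit: chi2 = n
hwe_test <- function(n_hom_major, n_het, n_hom_minor,
                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_hom_major + n_het + n_hom_minor
  if (any(n <= 0)) stop("total genotype count must be positive", call. = FALSE)
  if (method == "chisq") {
    p <- (2 * n_hom_major + n_het) / (2 * n)
    q <- 1 - p
    mono <- p == 0 | q == 0
    e <- cbind(n * p^2, n * 2 * p * q, n * q^2)
    o <- cbind(n_hom_major, n_het, n_hom_minor)
    chi2 <- rowSums((o - e)^2 / e)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    chi2[mono] <- NA_real_
    pval[mono] <- NA_real_
    out_method <- ifelse(mono, "not applicable (monomorphic)", "chisq")
    tibble::tibble(chi2 = chi2, p_value = pval, method = out_method)
  } else {
    stopifnot(length(n) == 1)
    pval <- hwe_exact_p(n_hom_major, n_het, n_hom_minor)
    tibble::tibble(chi2 = NA_real_, p_value = pval,
                   method = if (is.na(pval)) "not applicable (monomorphic)" else "exact")
  }
}

# Exact HWE p-value: probability of heterozygote counts no more likely than
# the observed one, conditional on the allele counts.
hwe_exact_p <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  if (n_minor == 0 || n_minor == 2 * n) return(NA_real_)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  log_prob <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(n - (n_minor + hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

#' Concordance between duplicated samples
#'
#' Genotyping runs typically re-assay a fraction of samples; the fraction of
#' matching calls among pairs where both calls are non-missing estimates the
#' genotyping error rate. Calls are compared as unordered allele pairs.
#'
#' @param genotypes Genotype tibble containing both members of every pair.
#' @param pairs Two-column data frame of subject ids (`original`,
#'   `duplicate`).
#' @return List with `concordance` (fraction, `NA` when nothing was
#'   comparable), `n_compared` and `n_discordant`.
#' @export
duplicate_concordance <- function(genotypes, pairs) {
  if (nrow(pairs) < 1) stop("at least one duplicate pair is required", call. = FALSE)
  snps <- setdiff(names(genotypes), "subject_id")
  i1 <- match(pairs[[1]], genotypes$subject_id)
  i2 <- match(pairs[[2]], genotypes$subject_id)
  if (anyNA(i1) || anyNA(i2)) stop("pair subject ids not found in genotypes", call. = FALSE)
  a <- apply(as.matrix(genotypes[i1, snps]), 2, normalize_call)
  b <- apply(as.matrix(genotypes[i2, snps]), 2, normalize_call)
  comparable <- !is.na(a) & !is.na(b)
  n_compared <- sum(comparable)
  if (n_compared == 0) {
    warning("no comparable (both non-missing) calls among duplicate pairs")
    return(list(concordance = NA_real_, n_compared = 0L, n_discordant = NA_integer_))
  }
  n_disc <- sum(a[comparable] != b[comparable])
  list(concordance = 1 - n_disc / n_compared,
       n_compared = n_compared, n_discordant = n_disc)
}

# Unordered allele-pair normalization: "A/C" and "C/A" are the same call.
normalize_call <- function(calls) {
  out <- calls
  out[out == ""] <- NA_character_
  idx <- which(!is.na(out))
  if (length(idx)) {
    parts <- strsplit(out[idx], "/", fixed = TRUE)
    out[idx] <- vapply(parts, function(p) paste(sort(p), collapse = "/"),
                       character(1))
  }
  out
}

#' Additive (effect-allele dosage) encoding
#'
#' Each call becomes the number of effect alleles it carries: 0 for the
#' homozygote without effect alleles, 1 for the heterozygote, 2 for the
#' effect-allele homozygote. Missing calls stay missing.
#'
#' @param genotypes Genotype tibble.
#' @param panel The matching [snp_panel()].
#' @return Tibble `subject_id` plus one integer dosage column per SNP.
#' @export
encode_additive <- function(genotypes, panel) {
  panel <- validate_panel(panel)
  out <- list(subject_id = genotypes$subject_id)
  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    if (!sid %in% names(genotypes)) {
      stop("genotype table lacks panel SNP ", sid, call. = FALSE)
    }
    calls <- genotypes[[sid]]
    calls[calls == ""] <- NA_character_
    dosage <- rep(NA_integer_, length(calls))
    idx <- which(!is.na(calls))
    if (length(idx)) {
      parts <- strsplit(calls[idx], "/", fixed = TRUE)
      lens <- lengths(parts)
      alle <- unlist(parts)
      valid <- c(panel$major_allele[i], panel$minor_allele[i])
      bad <- lens != 2 | vapply(parts, function(p) any(!p %in% valid), logical(1))
      if (any(bad)) {
        stop("invalid call for SNP ", sid, ", subject ",
             genotypes$subject_id[idx[which(bad)[1]]], ": '",
             calls[idx[which(bad)[1]]], "'", call. = FALSE)
      }
      m <- matrix(alle, ncol = 2, byrow = TRUE)
      dosage[idx] <- (m[, 1] == panel$effect_allele[i]) +
        (m[, 2] == panel$effect_allele[i])
    }
    out[[sid]] <- as.integer(dosage)
  }
  tibble::as_tibble(out)
}

#' Codominant (genotype-class) encoding
#'
#' Each SNP becomes a factor with the major-allele homozygote as reference
#' level, then the heterozygote, then the minor-allele homozygote, labelled
#' with the allele pairs (e.g. `"C/C" < "C/A" < "A/A"`). Genotype classes
#' absent from a sample simply drop at model time, collapsing the codominant
#' model to the contrasts that exist.
#'
#' @inheritParams encode_additive
#' @return Tibble `subject_id` plus one factor column per SNP.
#' @export
encode_codominant <- function(genotypes, panel) {
  panel <- validate_panel(panel)
  dosage <- encode_additive(genotypes, panel)  # validates calls
  out <- list(subject_id = genotypes$subject_id)
  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    M <- panel$major_allele[i]
    m <- panel$minor_allele[i]
    labs <- c(paste(M, M, sep = "/"), paste(M, m, sep = "/"),
              paste(m, m, sep = "/"))
    # dosage counts effect alleles; translate to minor-allele count so that
    # level order is always hom-major, het, hom-minor
    d <- dosage[[sid]]
    minor_count <- if (panel$effect_allele[i] == m) d else 2L - d
    out[[sid]] <- factor(labs[minor_count + 1L], levels = labs)
  }
  tibble::as_tibble(out)
}

#' Full genotype quality-control report
#'
#' Applies the subject call-rate filter, reports per-SNP call rates (SNPs are
#' reported but never auto-dropped), tests every SNP for Hardy-Weinberg
#' equilibrium on the filtered subjects, and, when duplicate pairs are given,
#' their concordance.
#'
#' @inheritParams encode_additive
#' @param call_rate_threshold Subject call-rate cut, default 0.80.
#' @param duplicate_pairs Optional two-column data frame of duplicated
#'   subject ids.
#' @param hwe_method Passed to [hwe_test()].
#' @return A list of class `qc_report`: `kept` (filtered genotypes),
#'   `discarded_subjects`, `subject_call_rates`, `snp_call_rates`, `hwe`
#'   (tibble per SNP with genotype counts, chi2, p), and
#'   `duplicate_concordance` (or `NULL`).
#' @export
genotype_qc <- function(genotypes, panel, call_rate_threshold = 0.80,
                        duplicate_pairs = NULL, hwe_method = "chisq") {
  panel <- validate_panel(panel)
  filt <- subject_call_rate_filter(genotypes, call_rate_threshold)
  rates <- call_rates(genotypes)
  cod <- encode_codominant(filt$kept, panel)
  counts <- t(vapply(panel$snp_id, function(sid) {
    tab <- table(factor(as.integer(cod[[sid]]), levels = 1:3))
    as.integer(tab)
  }, integer(3)))
  hwe <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    hwe_test(counts[i, 1], counts[i, 2], counts[i, 3], method = hwe_method)
  }))
  hwe <- dplyr::bind_cols(
    tibble::tibble(snp_id = panel$snp_id,
                   n_hom_major = counts[, 1], n_het = counts[, 2],
                   n_hom_minor = counts[, 3]),
    hwe)
  dup <- if (!is.null(duplicate_pairs)) {
    duplicate_concordance(genotypes, duplicate_pairs)
  }
  structure(list(
    kept = filt$kept,
    discarded_subjects = filt$discarded,
    subject_call_rates = rates$subject,
    snp_call_rates = rates$snp,
    hwe = hwe,
    duplicate_concordance = dup,
    call_rate_threshold = call_rate_threshold
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  %d subjects kept, %d discarded (call rate < %.0f%%)\n",
              nrow(x$kept), length(x$discarded_subjects),
              100 * x$call_rate_threshold))
  cat(sprintf("  mean SNP call rate %.1f%%\n",
              100 * mean(x$snp_call_rates$call_rate)))
  cat(sprintf("  HWE p-values: min %.3g\n", min(x$hwe$p_value, na.rm = TRUE)))
  if (!is.null(x$duplicate_concordance)) {
    cat(sprintf("  duplicate concordance %.3f (%d calls)\n",
                x$duplicate_concordance$concordance,
                x$duplicate_concordance$n_compared))
  }
  invisible(x)
}
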