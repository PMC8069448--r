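# Call-rate filtering, HWE testing, duplicate concordance, dosage encodings.

test_that("call-rate filter keeps 9/11 and discards 8/11 subjects", {
  g <- genotypes_with_missing(c(2, 3, 0))  # call rates 9/11, 8/11, 11/11
  f <- subject_call_rate_filter(g, threshold = 0.80)
  expect_identical(f$discarded, g$subject_id[2])
  expect_identical(f$kept$subject_id, g$subject_id[c(1, 3)])
  expect_equal(unname(f$call_rate), c(9, 8, 11) / 11)
})

test_that("engineered missingness discards exactly the brute-force tally", {
  co <- simulate_cohort(cohort_config(n_subjects = 300, seed = 55,
                                      missing_rate = 0.15))
  f <- subject_call_rate_filter(co$genotypes, threshold = 0.80)
  calls <- as.matrix(co$genotypes[, -1])
  brute <- co$genotypes$subject_id[rowSums(!is.na(calls)) / ncol(calls) < 0.80]
  expect_identical(f$discarded, brute)
  expect_gt(length(brute), 0)  # the scenario actually exercises the filter
})

test_that("filtering and encoding commute", {
  panel <- default_tel_panel()
  co <- simulate_cohort(cohort_config(n_subjects = 120, seed = 56,
                                      missing_rate = 0.15))
  f <- subject_call_rate_filter(co$genotypes, 0.8)
  a <- encode_additive(f$kept, panel)
  b <- encode_additive(co$genotypes, panel)
  b <- b[b$subject_id %in% f$kept$subject_id, ]
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("HWE chi-square matches hand-computed expectations", {
  r <- hwe_test(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  # independent expected-count oracle for (30, 50, 20)
  n <- 100
  p <- (2 * 30 + 50) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2_oracle <- sum((c(30, 50, 20) - expected)^2 / expected)
  r2 <- hwe_test(30, 50, 20)
  expect_equal(r2$chi2, chi2_oracle, tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(chi2_oracle, 1, lower.tail = FALSE))

  # complete heterozygote deficit: chi2 equals the sample size
  r3 <- hwe_test(50, 0, 50)
  expect_equal(r3$chi2, 100)
  expect_lt(r3$p_value, 1e-20)
})

test_that("monomorphic SNPs report HWE as not applicable", {
  r <- hwe_test(100, 0, 0)
  expect_true(is.na(r$p_value))
  expect_match(r$method, "not applicable")
  expect_true(is.na(hwe_test(100, 0, 0, method = "exact")$p_value))
})

test_that("the exact HWE test is sane and near the chi-square for common alleles", {
  r_exact <- hwe_test(120, 60, 20, method = "exact")
  r_chi <- hwe_test(120, 60, 20)
  expect_gt(r_exact$p_value, 0)
  expect_lte(r_exact$p_value, 1)
  expect_lt(abs(log10(r_exact$p_value) - log10(r_chi$p_value)), 1)
  # a tiny table enumerable by hand: 2 minor alleles among n = 3 genotypes,
  # so the het count is 0 (one minor homozygote) or 2; multinomial weights
  # n! / (n_AA! n_Aa! n_aa!) * 2^het give 3 and 12
  w0 <- factorial(3) / (factorial(1) * factorial(0) * factorial(2)) * 2^0
  w2 <- factorial(3) / (factorial(0) * factorial(2) * factorial(1)) * 2^2
  expect_equal(hwe_test(2, 0, 1, method = "exact")$p_value,
               w0 / (w0 + w2), tolerance = 1e-12)
})

test_that("HWE p-values are approximately uniform under the null", {
  set.seed(31)
  n <- 5000
  q <- 0.3
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  counts <- stats::rmultinom(1000, n, probs)
  p <- hwe_test(counts[1, ], counts[2, ], counts[3, ])$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicate concordance counts discordant calls", {
  g <- genotypes_with_missing(rep(0, 4), seed = 3)
  g2 <- g
  g2$subject_id <- paste0(g$subject_id, "_dup")
  both <- dplyr::bind_rows(g, g2)
  pairs <- data.frame(a = g$subject_id, b = g2$subject_id)
  expect_equal(duplicate_concordance(both, pairs)$concordance, 1)

  # one discordant call out of 11 compared in one pair
  g3 <- g2
  snp <- default_tel_panel()$snp_id[1]
  g3[[snp]][1] <- if (g[[snp]][1] == "C/C") "C/A" else "C/C"
  both3 <- dplyr::bind_rows(g[1, ], g3[1, ])
  r <- duplicate_concordance(both3, data.frame(a = g$subject_id[1],
                                               b = g3$subject_id[1]))
  expect_equal(r$concordance, 10 / 11)
  expect_equal(r$n_compared, 11L)
})

test_that("allele order does not affect concordance", {
  g <- tibble::tibble(subject_id = c("a", "b"), rs1 = c("C/A", "A/C"))
  r <- duplicate_concordance(g, data.frame("a", "b"))
  expect_equal(r$concordance, 1)
})

test_that("simulated 1% flip rate yields ~99% concordance", {
  panel <- default_tel_panel()
  g <- simulate_genotypes(panel, 50, missing_rate = 0, seed = 8)
  dup <- g
  dup$subject_id <- paste0(g$subject_id, "_d")
  set.seed(9)
  flips <- 0
  for (j in panel$snp_id) {
    flip <- runif(50) < 0.01
    flips <- flips + sum(flip)
    swap <- paste(panel$major_allele[match(j, panel$snp_id)],
                  panel$minor_allele[match(j, panel$snp_id)], sep = "/")
    dup[[j]][flip] <- ifelse(dup[[j]][flip] == swap,
                             paste(rep(panel$major_allele[match(j, panel$snp_id)], 2),
                                   collapse = "/"), swap)
  }
  r <- duplicate_concordance(dplyr::bind_rows(g, dup),
                             data.frame(g$subject_id, dup$subject_id))
  expect_equal(r$n_discordant, flips)
  se <- sqrt(0.01 * 0.99 / 550)
  expect_lt(abs(r$concordance - 0.99), 4 * se + 1e-9)
})

test_that("additive dosage counts effect alleles regardless of call order", {
  panel <- snp_panel("rs1", "G", "C", "A", "A", weight = 1, maf = 0.2)
  g <- tibble::tibble(subject_id = c("s1", "s2", "s3", "s4"),
                      rs1 = c("C/C", "C/A", "A/A", "A/C"))
  d <- encode_additive(g, panel)
  expect_identical(d$rs1, c(0L, 1L, 2L, 1L))
  # effect allele can be the major allele
  panel2 <- snp_panel("rs1", "G", "C", "A", "C", weight = 1, maf = 0.2)
  expect_identical(encode_additive(g, panel2)$rs1, c(2L, 1L, 0L, 1L))
})

test_that("invalid alleles raise an error naming subject and SNP", {
  panel <- snp_panel("rs1", "G", "C", "A", "A", weight = 1, maf = 0.2)
  g <- tibble::tibble(subject_id = c("s1", "s2"), rs1 = c("C/C", "C/G"))
  expect_error(encode_additive(g, panel), "rs1.*s2")
})

test_that("codominant coding references the major-allele homozygote", {
  panel <- snp_panel("rs1", "G", "T", "A", "A", weight = 1, maf = 0.1)
  g <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                      rs1 = c("T/T", "T/A", "T/T", "A/A", "T/A", NA))
  cod <- encode_codominant(g, panel)
  expect_identical(levels(cod$rs1), c("T/T", "T/A", "A/A"))
  expect_identical(as.integer(cod$rs1), c(1L, 2L, 1L, 3L, 2L, NA))
  # indicator sums equal class counts in a full three-class SNP
  mm <- stats::model.matrix(~rs1, data = cod)
  expect_equal(unname(colSums(mm)[-1]), c(2, 1))
})

test_that("dosage column means recover effect-allele frequencies", {
  panel <- default_tel_panel()
  g <- simulate_genotypes(panel, 50000, missing_rate = 0.02, seed = 44)
  d <- encode_additive(g, panel)
  freq_hat <- colMeans(as.matrix(d[panel$snp_id]), na.rm = TRUE) / 2
  f <- ifelse(panel$effect_allele == panel$minor_allele, panel$maf,
              1 - panel$maf)
  expect_true(all(abs(freq_hat - f) < 0.01))
})

test_that("the QC report assembles filter, HWE and concordance", {
  co <- simulate_cohort(cohort_config(n_subjects = 200, seed = 58,
                                      missing_rate = 0.1))
  g <- co$genotypes
  dup <- g[1:10, ]
  dup$subject_id <- paste0(dup$subject_id, "_dup")
  rep_g <- dplyr::bind_rows(g, dup)
  qc <- genotype_qc(rep_g, co$panel,
                    duplicate_pairs = data.frame(g$subject_id[1:10],
                                                 dup$subject_id))
  expect_s3_class(qc$hwe, "tbl_df")
  expect_equal(nrow(qc$hwe), 11)
  expect_true(all(qc$hwe$p_value > 1e-6, na.rm = TRUE))
  expect_equal(qc$duplicate_concordance$concordance, 1)
  expect_true(all(qc$subject_call_rates$call_rate[
    match(qc$discarded_subjects, qc$subject_call_rates$subject_id)] < 0.8))
  expect_output(print(qc), "Genotype QC report")
})
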