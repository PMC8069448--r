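# Adjusted linear models, plate random effects, the scan, Bonferroni flags.

test_that("fit_linear agrees with stats::lm to numerical precision", {
  set.seed(11)
  d <- tibble::tibble(age = runif(300, 18, 59), smoker = runif(300) < 0.3,
                      x = rnorm(300))
  d$y <- 1 + 0.5 * d$x - 0.02 * d$age + 0.3 * d$smoker + rnorm(300)
  rec <- fit_linear(d, "y", "x")
  ref <- stats::lm(y ~ x + age + smoker, data = d)
  expect_equal(rec$coefficient, unname(coef(ref)["x"]), tolerance = 1e-10)
  ci <- stats::confint(ref)["x", ]
  expect_equal(c(rec$ci_low, rec$ci_high), unname(ci), tolerance = 1e-10)
  expect_equal(rec$p_value, summary(ref)$coefficients["x", 4],
               tolerance = 1e-10)
  expect_equal(rec$n, 300L)
})

test_that("an injected effect is recovered within its confidence interval", {
  set.seed(12)
  d <- tibble::tibble(age = runif(2000, 18, 59), smoker = runif(2000) < 0.3,
                      x = rnorm(2000))
  d$y <- 0.5 * d$x + rnorm(2000)
  rec <- fit_linear(d, "y", "x")
  expect_true(rec$ci_low <= 0.5 && 0.5 <= rec$ci_high)
  expect_lt(abs(rec$coefficient - 0.5), 0.1)
})

test_that("degenerate designs are refused with the offending term named", {
  set.seed(13)
  d <- tibble::tibble(age = runif(50, 18, 59), smoker = runif(50) < 0.3,
                      x = rnorm(50))
  d$y <- rnorm(50)
  d$x_copy <- d$x
  expect_error(fit_linear(d, "y", "x", covariates = c("age", "smoker", "x_copy", "x")),
               "collinear")
  d$const <- 1
  expect_error(fit_linear(d, "y", "const"), "constant")
  d$onecat <- factor(rep("a", 50))
  expect_error(fit_linear(d, "y", "onecat"), "single class")
})

test_that("too few complete cases skips the model with a message", {
  d <- tibble::tibble(age = runif(20, 18, 59), smoker = runif(20) < 0.5,
                      x = c(rnorm(5), rep(NA, 15)), y = rnorm(20))
  expect_message(rec <- fit_linear(d, "y", "x"), "complete cases")
  expect_equal(nrow(rec), 0)
})

test_that("factor exposures emit one contrast per non-reference level", {
  set.seed(14)
  d <- tibble::tibble(age = runif(500, 18, 59), smoker = runif(500) < 0.3,
                      q = factor(paste0("Q", sample(1:5, 500, TRUE)),
                                 levels = paste0("Q", 1:5)),
                      y = rnorm(500))
  rec <- fit_linear(d, "y", "q")
  expect_equal(nrow(rec), 4)
  expect_equal(rec$term, paste(paste0("Q", 2:5), "vs Q1"))
  # a two-class genotype collapses to one contrast
  d$g <- factor(sample(c("T/T", "T/A"), 500, TRUE), levels = c("T/T", "T/A", "A/A"))
  rec2 <- fit_linear(d, "y", "g")
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$term, "T/A vs T/T")
})

test_that("the plate mixed model collapses to OLS when plate variance is nil", {
  set.seed(15)
  n <- 400
  d <- tibble::tibble(age = runif(n, 18, 59), smoker = runif(n) < 0.3,
                      x = rnorm(n), plate = sample(1:8, n, TRUE))
  d$y <- 0.3 * d$x + rnorm(n)  # no plate effect at all
  mix <- fit_plate_mixed(d, "y", "x")
  ols <- fit_linear(d, "y", "x")
  expect_lt(abs(mix$coefficient - ols$coefficient), 1e-6)
})

test_that("the plate mixed model recovers effects under strong plate structure", {
  set.seed(16)
  n <- 599
  plate <- sample(1:46, n, TRUE)
  offs <- rnorm(46, 0, 1)
  d <- tibble::tibble(age = runif(n, 18, 59), smoker = runif(n) < 0.3,
                      x = rnorm(n), plate = plate)
  d$y <- 0.25 * d$x + offs[plate] + rnorm(n, 0, 0.4)
  rec <- fit_plate_mixed(d, "y", "x")
  expect_true(rec$ci_low <= 0.25 && 0.25 <= rec$ci_high)
  # with a single plate it falls back to OLS with a warning
  d1 <- d
  d1$plate <- 1
  expect_warning(rec1 <- fit_plate_mixed(d1, "y", "x"), "single plate")
  ols1 <- fit_linear(d1, "y", "x")
  expect_equal(rec1$coefficient, ols1$coefficient, tolerance = 1e-10)
})

test_that("type-I error of the mixed model stays nominal under plate noise", {
  set.seed(17)
  hits <- 0
  B <- 200
  for (i in 1:B) {
    n <- 150
    plate <- sample(1:10, n, TRUE)
    offs <- rnorm(10, 0, 1)
    d <- tibble::tibble(age = runif(n, 18, 59), smoker = runif(n) < 0.3,
                        x = rnorm(n), plate = plate,
                        y = offs[plate] + rnorm(n))
    hits <- hits + (fit_plate_mixed(d, "y", "x")$p_value < 0.05)
  }
  expect_gt(hits / B, 0.01)
  expect_lt(hits / B, 0.11)
})

test_that("the scan enumerates the full design without silent drops", {
  co <- simulate_cohort(cohort_config(n_subjects = 250, seed = 23))
  res <- analyze_cohort(co)
  rec <- res$records
  outs <- c(names(default_age_betas()), "abcd_total", "abcd_mot")

  # 11 SNPs x additive x each sperm outcome -> 11 records per outcome
  add_conc <- rec[rec$form == "additive" & rec$outcome == "concentration", ]
  expect_equal(nrow(add_conc), 11)

  # additive: one record per SNP per outcome (sperm outcomes + log STL)
  expect_equal(sum(rec$form == "additive"), 11 * (length(outs) + 1))

  # codominant count: per SNP, genotype classes present in the analysis
  # sample minus 1, counted separately for the sperm outcomes (all
  # phenotypes complete) and for the log STL outcome (usable STL only)
  cod <- encode_codominant(res$qc$kept, co$panel)
  classes <- vapply(co$panel$snp_id,
                    function(s) length(unique(stats::na.omit(cod[[s]]))),
                    integer(1))
  stl_ids <- res$stl$subject_id[res$stl$usable]
  cod_stl <- cod[cod$subject_id %in% stl_ids, ]
  classes_stl <- vapply(co$panel$snp_id,
                        function(s) length(unique(stats::na.omit(cod_stl[[s]]))),
                        integer(1))
  expect_equal(sum(rec$form == "codominant"),
               sum(classes - 1) * length(outs) + sum(classes_stl - 1))

  # STL: linear + 4 quintile contrasts per sperm outcome
  stl_rec <- rec[rec$exposure == "stl", ]
  expect_equal(nrow(stl_rec), length(outs) * 5)

  # teloscores: (linear + 4 quintiles) x (sperm outcomes + log STL) x 2 scores
  for (sc in c("teloscore_unweighted", "teloscore_weighted")) {
    expect_equal(sum(rec$exposure == sc), (length(outs) + 1) * 5)
  }
  expect_length(attr(rec, "skipped"), 0)
})

test_that("two-genotype SNPs contribute a single codominant contrast", {
  panel <- default_tel_panel()
  rare <- panel[panel$snp_id == "rs6772228", ]
  g <- tibble::tibble(subject_id = sprintf("S%03d", 1:200),
                      rs6772228 = sample(c("T/T", "T/A"), 200, TRUE,
                                         prob = c(0.9, 0.1)))
  cod <- encode_codominant(g, rare)
  d <- tibble::tibble(age = runif(200, 18, 59), smoker = runif(200) < 0.3,
                      g = cod$rs6772228, y = rnorm(200))
  rec <- fit_linear(d, "y", "g")
  expect_equal(rec$term, "T/A vs T/T")
})

test_that("Bonferroni flags use 0.05/33 on SNP records only", {
  rec <- tibble::tibble(
    outcome = "y", exposure = c("rs1", "rs1", "stl"),
    form = c("additive", "codominant", "linear"),
    term = "t", n = 100L,
    coefficient = 1, ci_low = 0, ci_high = 2,
    p_value = c(0.0014, 0.009, 0.0001))
  out <- apply_multiple_testing(rec, alpha = 0.05, m = 33)
  expect_equal(signif(attr(out, "bonferroni_threshold"), 2), 0.0015)
  expect_true(out$significant_bonferroni[1])    # 0.0014 < 0.05/33
  expect_false(out$significant_bonferroni[2])   # 0.009 does not survive
  expect_true(is.na(out$significant_bonferroni[3]))  # not part of the SNP scan
  expect_true(out$significant_nominal[3])
  # m = 1 reduces the flag to the nominal comparison
  out1 <- apply_multiple_testing(rec, alpha = 0.05, m = 1)
  expect_identical(out1$significant_bonferroni[1:2],
                   out1$significant_nominal[1:2])
})
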