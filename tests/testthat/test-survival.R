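toy_signature <- function(genes) {
  gene_signature("toy", data.frame(gene = genes, direction = "E",
                                   rank = seq_along(genes),
                                   effect_size = NA_real_,
                                   stringsAsFactors = FALSE))
}

test_that("subtype classification follows the marker-probe rule", {
  expect_identical(classify_subtype(600, 300, 1000), "luminalA")
  expect_identical(classify_subtype(600, 300, 5000), "luminalB")
  expect_identical(classify_subtype(600, 900, 1000), "luminalB")
  expect_identical(classify_subtype(100, 900, 100), "basal")
  expect_identical(classify_subtype(100, 300, 5000), "HER2")
  expect_warning(out <- classify_subtype(NA, 300, 100), "unclassified")
  expect_identical(out, "unclassified")
})

test_that("every complete record receives exactly one of the four labels", {
  set.seed(8)
  lab <- classify_subtype(runif(500, 0, 1000), runif(500, 0, 1000),
                          runif(500, 0, 10000))
  expect_true(all(lab %in% c("luminalA", "luminalB", "basal", "HER2")))
})

test_that("signature scores are the mean over present genes", {
  sig <- toy_signature(c("a", "b"))
  expect_equal(as.numeric(score_signature(c(a = 1, b = 1), sig)), 1)
  expect_equal(as.numeric(score_signature(c(a = 2, b = 4), sig)), 3)
  sig3 <- toy_signature(c("a", "b", "zz"))
  expect_warning(s <- score_signature(c(a = 2, b = 4, other = 99), sig3),
                 "absent")
  expect_equal(as.numeric(s), 3)
  expect_identical(attr(s, "n_missing"), 1L)
  expect_error(score_signature(c(x = 1), sig), "no signature gene")
})

test_that("Kaplan-Meier estimate matches hand computations", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  km_cens <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_cens$survival, c(2 / 3, 1 / 3, 1 / 3))

  # censoring at 2: S(1) = 2/3, then 1 at risk at t=3 -> S(3) = 0
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)

  all_cens <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(12)
  t <- round(rexp(60, 0.1), 2)
  km <- kaplan_meier(t, rep(1, 60))
  expect_equal(km$survival, 1 - ecdf(t)(km$time))
})

test_that("logrank statistic matches a hand risk-table computation", {
  # A events at 1, 2; B events at 3, 4; frozen hand computation:
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi2 = (7/6)^2 / (17/36)
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$o_minus_e, 7 / 6)
  expect_equal(lr$chi2, (7 / 6)^2 / (17 / 36))

  same <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("logrank agrees with survival::survdiff and is label-symmetric", {
  set.seed(31)
  for (i in 1:5) {
    d <- generate_twogroup_survival(n = 80, hr = 1.8, seed = 300 + i)
    a <- d[d$high, ]; b <- d[!d$high, ]
    lr <- logrank_test(a$time, a$event, b$time, b$event)
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ high, data = d)
    expect_equal(lr$chi2, sd_fit$chisq, tolerance = 1e-8)
    swapped <- logrank_test(b$time, b$event, a$time, a$event)
    expect_equal(swapped$chi2, lr$chi2)
    expect_equal(swapped$p, lr$p)
  }
})

test_that("logrank detects a true hazard ratio of 2 with high power", {
  rejections <- vapply(1:60, function(s) {
    d <- generate_twogroup_survival(n = 300, hr = 2, censor_frac = 0.2,
                                    seed = 4000 + s)
    a <- d[d$high, ]; b <- d[!d$high, ]
    logrank_test(a$time, a$event, b$time, b$event)$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.8)
})

test_that("Cox fit is neutral for identical groups and CI brackets the HR", {
  t <- c(1, 2, 3, 4)
  e <- c(1, 1, 0, 1)
  # identical survival experience in both groups
  fit <- cox_hr(rep(c(TRUE, FALSE), each = 4), c(t, t), c(e, e))
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_lte(fit$ci_low, fit$hr)
  expect_gte(fit$ci_high, fit$hr)
})

test_that("Cox recovers a simulated hazard ratio of 2 at n = 1000", {
  d <- generate_twogroup_survival(n = 1000, hr = 2, censor_frac = 0.2,
                                  seed = 77)
  fit <- cox_hr(d$high, d$time, d$event)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.3)
  expect_false(fit$diverged)
})

test_that("complete separation is flagged rather than crashing", {
  t <- c(1, 2, 3, 10, 11, 12)
  e <- c(1, 1, 1, 0, 0, 0)
  fit <- suppressWarnings(cox_hr(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                                 t, e))
  expect_true(fit$diverged)
  expect_true(is.infinite(fit$hr))
})

test_that("best-cutoff search picks the median when the hazard steps there", {
  scores <- 1:40
  time <- c(seq(10, 11, length.out = 20), seq(1, 2, length.out = 20))
  event <- rep(1, 40)
  sel <- select_best_cutoff(scores, time, event)
  expect_equal(sel$quantile, 0.5)
  expect_equal(min(sel$candidate_p), sel$p)
  expect_error(select_best_cutoff(rep(1, 40), time, event), "degenerate")
})

test_that("signature survival evaluation recovers the planted direction", {
  sig <- toy_signature(sprintf("u%04d", 1:10))
  pos <- generate_cohort(250, sig, beta = 0.8, n_genes = 150, seed = 41)
  fit_pos <- evaluate_signature_survival(pos$cohort, sig)
  expect_gt(fit_pos$hr, 1)
  expect_lt(fit_pos$logrank_p, 0.01)

  neg <- generate_cohort(250, sig, beta = -0.8, n_genes = 150, seed = 42)
  fit_neg <- evaluate_signature_survival(neg$cohort, sig)
  expect_lt(fit_neg$hr, 1)
  expect_lt(fit_neg$logrank_p, 0.01)
})

test_that("subtype filtering restricts the analysis set", {
  sig <- toy_signature(sprintf("u%04d", 1:10))
  gen <- generate_cohort(400, sig, beta = 0.8, n_genes = 150, seed = 43)
  fit_basal <- evaluate_signature_survival(gen$cohort, sig,
                                           subtype = "basal")
  n_basal <- sum(gen$cohort$meta$subtype == "basal")
  expect_identical(fit_basal$n_high + fit_basal$n_low, n_basal)
})

test_that("cohorts round-trip through CSV", {
  sig <- toy_signature(sprintf("u%04d", 1:5))
  gen <- generate_cohort(40, sig, beta = 0.3, n_genes = 60, seed = 44)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(gen$cohort, f)
  back <- read_cohort(f)
  expect_equal(back$expression, gen$cohort$expression, tolerance = 1e-12)
  expect_identical(back$meta$subtype, gen$cohort$meta$subtype)
})
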