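test_that("Weibull MLE recovers parameters and matches independent fitters", {
  set.seed(101)
  x <- rweibull(200, 1.3, 0.01)
  fit <- fit_weibull_background(x, floor_eps = 2.5e-4)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$shape - 1.3) / 1.3, 0.15)
  expect_lt(abs(fit$scale - 0.01) / 0.01, 0.10)

  # independent grid-search MLE oracle
  grid <- grid_mle_weibull(x)
  expect_lt(abs(fit$shape - grid["shape"]) / grid["shape"], 0.01)
  expect_lt(abs(fit$scale - grid["scale"]) / grid["scale"], 0.01)

  # second independent route
  skip_if_not_installed("fitdistrplus")
  fd <- fitdistrplus::fitdist(x, "weibull")
  expect_lt(abs(fit$shape - fd$estimate["shape"]) / fit$shape, 0.01)
  expect_lt(abs(fit$scale - fd$estimate["scale"]) / fit$scale, 0.01)
})

test_that("the exponential special case is recovered", {
  set.seed(7)
  x <- rexp(500, rate = 100)     # Weibull shape 1, scale = mean 0.01
  fit <- fit_weibull_background(x, floor_eps = 1e-5)
  expect_gt(fit$shape, 0.85)
  expect_lt(fit$shape, 1.15)
  # closed-form exponential MLE for the scale at shape 1 is the sample mean
  expect_lt(abs(fit$scale - mean(x)) / mean(x), 0.1)
})

test_that("degenerate and underpowered control sets are flagged unusable", {
  same <- fit_weibull_background(rep(0.01, 10), floor_eps = 1e-4)
  expect_identical(same$shape, 50)
  expect_true(same$degenerate)
  expect_false(same$fit_ok)

  few <- fit_weibull_background(c(0.01, 0.02), floor_eps = 1e-4)
  expect_false(few$fit_ok)

  # all-zero controls with the floor disabled cannot be fitted
  zeros <- fit_weibull_background(rep(0, 8), floor_eps = 0)
  expect_false(zeros$fit_ok)

  expect_error(fit_weibull_background(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the upper-tail p-value obeys its closed-form identities", {
  set.seed(3)
  fit <- fit_weibull_background(rweibull(100, 1.5, 0.01), floor_eps = 2e-4)
  # at the scale point the survival is exp(-1) whatever the shape
  expect_equal(weibull_pvalue(fit, fit$scale), exp(-1))
  # a zero VAF is floored
  expect_equal(weibull_pvalue(fit, 0),
               exp(-(fit$floor_eps / fit$scale)^fit$shape))
  expect_gt(weibull_pvalue(fit, 0), 0.99)

  # direct evaluation at a fixed parameterisation
  man <- fit
  man$shape <- 1.3
  man$scale <- 0.01
  expect_equal(weibull_pvalue(man, 0.30), exp(-30^1.3))

  # numeric-integration oracle for the survival probability
  for (v in c(0.002, 0.01, 0.03)) {
    num <- integrate(function(t) dweibull(t, fit$shape, fit$scale),
                     lower = v, upper = Inf, rel.tol = 1e-13)$value
    expect_lt(abs(weibull_pvalue(fit, v) - num) / num, 1e-10)
  }

  # p is strictly decreasing in VAF
  vs <- seq(0.001, 0.2, by = 0.001)
  expect_true(all(diff(weibull_pvalue(fit, vs)) < 0))

  expect_error(weibull_pvalue(fit_weibull_background(rep(0.01, 8),
                                                     floor_eps = 1e-4),
                              0.1),
               "not usable")
})

test_that("BH adjustment matches hand computation and is order-equivariant", {
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_equal(fdr_adjust(0.01), 0.01)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
})

test_that("positivity calling separates signal from stutter background", {
  panel <- tiny_panel()
  cohort <- make_cohort_specs(panel, seed = 31, n_controls = 8,
                              n_tumors = 10, n_planted = 8,
                              planted_loci = "locA", vaf = 0.3)
  counts <- cohort_counts(panel, cohort)
  calls <- suppressWarnings(call_positives(counts, cohort$sheet))
  at_planted <- calls[calls$locus_id == "locA" & calls$offset == -1, ]
  planted_ids <- sprintf("tu_%02d", 1:8)
  expect_true(all(at_planted$positive[at_planted$sample_id %in% planted_ids]))
  # q-values of the planted events are overwhelming
  expect_lt(max(at_planted$q_value[at_planted$sample_id %in% planted_ids]),
            1e-6)
  # frequency table agrees with the call matrix
  freq <- mutation_frequency(calls, cohort$sheet)
  f <- freq[freq$locus_id == "locA" & freq$offset == -1, ]
  expect_identical(f$n_samples, 10L)
  expect_identical(f$n_positive,
                   sum(at_planted$positive))
  # controls are never tested
  expect_false(any(grepl("^wt_", calls$sample_id)))
})

test_that("a tumour VAF at the control median is not called positive", {
  set.seed(12)
  ctl <- rweibull(8, 2, 0.008)
  fit <- fit_weibull_background(ctl, floor_eps = 2.5e-4)
  expect_gt(weibull_pvalue(fit, median(ctl)), 0.3)
})

test_that("indels without a usable background fall back to the binomial test", {
  panel <- tiny_panel()
  counts <- data.frame(
    sample_id = rep(c(paste0("wt", 1:8), "tu1"), times = 1),
    locus_id = "locA", offset = -1L,
    mutant_reads = c(rep(0L, 8), 40L),
    wt_reads = rep(1000L, 9), total_usable = rep(1000L, 9),
    vaf = c(rep(0, 8), 40 / 1040))
  sheet <- data.frame(sample_id = c(paste0("wt", 1:8), "tu1"),
                      group = c(rep("wt_control", 8), "tumor"))
  expect_warning(calls <- call_positives(counts, sheet), "binomial fallback")
  expect_identical(calls$method, "binomial")
  # oracle: exact upper binomial tail at the floored background rate
  p0 <- 1 / (2 * 1000)
  expect_equal(calls$p_value,
               pbinom(39, 1040, p0, lower.tail = FALSE))
  expect_true(calls$positive)
})

test_that("alpha thresholding is strict, monotone, and raw mode works", {
  panel <- tiny_panel()
  cohort <- make_cohort_specs(panel, seed = 55, n_controls = 8,
                              n_tumors = 6, n_planted = 3,
                              planted_loci = "locB", vaf = 0.4)
  counts <- cohort_counts(panel, cohort)
  strict <- suppressWarnings(call_positives(counts, cohort$sheet, alpha = 0.05))
  loose <- suppressWarnings(call_positives(counts, cohort$sheet, alpha = 1))
  expect_true(all(loose$positive[strict$positive]))
  planted <- loose$locus_id == "locB" & loose$offset == -1 &
    loose$sample_id %in% sprintf("tu_%02d", 1:3)
  expect_true(all(loose$positive[planted]))
  raw <- suppressWarnings(call_positives(counts, cohort$sheet, threshold = "raw"))
  expect_equal(raw$positive, raw$p_value < 0.05)
  expect_error(call_positives(counts, cohort$sheet, alpha = 0), "alpha")
})
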