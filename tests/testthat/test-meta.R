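test_that("standard errors recovered from printed confidence intervals", {
  expect_equal(se_from_ci(0.88, 0.97),
               (log(0.97) - log(0.88)) / (2 * qnorm(0.975)))
  expect_equal(se_from_ci(0.88, 0.97), 0.0248, tolerance = 2e-3)
  # symmetric-on-log interval has the closed form 0.1 / z
  h <- 1.3
  expect_equal(se_from_ci(exp(-0.1) * h, exp(0.1) * h), 0.1 / qnorm(0.975),
               tolerance = 1e-12)
  expect_equal(se_from_ci(1, 1), 0)
  expect_error(se_from_ci(-1, 2), class = "survscan_bad_ci")
  # a zero-width interval gives se 0, which pooling must reject
  expect_error(
    fixed_effect_meta(tibble::tibble(cohort = "x", beta = 0, se = 0)),
    class = "survscan_bad_se"
  )
})

test_that("fixed-effects pooling obeys its closed forms", {
  one <- fixed_effect_meta(tibble::tibble(cohort = "a", beta = -0.1,
                                          se = 0.04))
  expect_equal(one$pooled_beta, -0.1)
  expect_equal(one$pooled_se, 0.04)

  two <- fixed_effect_meta(tibble::tibble(cohort = c("a", "b"),
                                          beta = -0.1, se = 0.04))
  expect_equal(two$pooled_beta, -0.1)
  expect_equal(two$pooled_se, 0.04 / sqrt(2))

  expect_error(fixed_effect_meta(tibble::tibble(beta = double(),
                                                se = double())),
               class = "survscan_empty_meta")
})

test_that("pooling the discovery and replication rows gives 0.95 (0.92-0.98)", {
  studies <- tibble::tibble(
    cohort = c("discovery", "replication_pooled"),
    hr = c(0.92, 0.97), ci_low = c(0.88, 0.93), ci_high = c(0.97, 1.00)
  )
  m <- fixed_effect_meta(studies)
  expect_equal(round(m$pooled_hr, 2), 0.95)
  expect_equal(round(m$ci_low, 2), 0.92)
  expect_equal(round(m$ci_high, 2), 0.98)
})

test_that("pooled estimates agree with an independent meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(61)
  est <- tibble::tibble(
    cohort = sprintf("c%d", 1:9),
    beta = rnorm(9, -0.05, 0.03),
    se = runif(9, 0.02, 0.12)
  )
  m <- fixed_effect_meta(est)
  rma <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
  expect_equal(m$pooled_beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$pooled_se, rma$se, tolerance = 1e-10)
  expect_equal(m$p, rma$pval, tolerance = 1e-10)
  expect_equal(m$q_stat, rma$QE, tolerance = 1e-8)
})

test_that("study order never changes the pooled numbers", {
  set.seed(62)
  est <- tibble::tibble(cohort = sprintf("c%d", 1:5),
                        beta = rnorm(5, 0, 0.1), se = runif(5, 0.02, 0.2))
  m1 <- fixed_effect_meta(est, cohort_order = est$cohort)
  m2 <- fixed_effect_meta(est[5:1, ], cohort_order = est$cohort)
  expect_equal(m1$pooled_beta, m2$pooled_beta)
  expect_equal(m1$pooled_se, m2$pooled_se)
  expect_equal(m1$direction, m2$direction)
})

test_that("pooled variance never exceeds any single study's variance", {
  set.seed(63)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    est <- tibble::tibble(cohort = sprintf("c%d", 1:k),
                          beta = rnorm(k), se = runif(k, 0.01, 0.5))
    m <- fixed_effect_meta(est)
    expect_lte(m$pooled_se, min(est$se))
  }
})

test_that("direction strings encode per-study effect signs in fixed order", {
  nine <- tibble::tibble(cohort = sprintf("c%d", 1:9), hr = rep(0.9, 9),
                         ci_low = rep(0.85, 9), ci_high = rep(0.95, 9))
  expect_equal(direction_string(nine), strrep("-", 9))

  mixed <- dplyr::mutate(nine, hr = replace(hr, 6, 1.1))
  expect_equal(direction_string(mixed), "-----+---")

  # missing cohort -> placeholder, and exact HR 1 -> "0"
  some <- tibble::tibble(cohort = c("a", "c"), hr = c(1, 0.8),
                         ci_low = c(0.9, 0.7), ci_high = c(1.1, 0.9))
  expect_equal(direction_string(some, cohort_order = c("a", "b", "c")),
               "0?-")
})

test_that("printed direction fields parse into consistency counts", {
  counts <- direction_counts("−−−−− + −−−")
  expect_equal(counts$n_studies, 9)
  expect_equal(counts$n_protective, 8)
  expect_equal(counts$n_risk, 1)
  expect_error(direction_counts("--x"), "unrecognized")
})

test_that("Bonferroni thresholds divide alpha by the validated SNP count", {
  expect_equal(round(bonferroni_threshold(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), class = "survscan_bad_k")
  m <- fixed_effect_meta(
    tibble::tibble(cohort = "a", beta = -0.05, se = 0.01),
    bonferroni_alpha = bonferroni_threshold(0.05, 3)
  )
  expect_true(m$significant)
})

test_that("leave-one-out behaves like pooling the remaining studies", {
  two <- tibble::tibble(cohort = c("a", "b"), beta = c(-0.1, 0.2),
                        se = c(0.05, 0.08))
  loo <- leave_one_out(two, "a")
  expect_equal(loo$pooled_beta, 0.2)
  expect_equal(loo$pooled_se, 0.08)
  expect_error(leave_one_out(two, "zz"), "not present")

  # excluding the most precise (largest-weight) study widens the CI
  set.seed(64)
  nine <- tibble::tibble(cohort = sprintf("c%d", 1:9),
                         beta = rnorm(9, -0.05, 0.02),
                         se = c(0.015, runif(8, 0.05, 0.2)))
  full <- fixed_effect_meta(nine)
  wo <- leave_one_out(nine, "c1")
  expect_gt(wo$pooled_se, full$pooled_se)
})

test_that("pooled CI coverage of a common effect is nominal", {
  set.seed(65)
  b <- -0.1
  ses <- c(0.03, 0.05, 0.08, 0.04, 0.1, 0.06, 0.15, 0.07, 0.05)
  covered <- 0L
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    est <- tibble::tibble(cohort = sprintf("c%d", 1:9),
                          beta = rnorm(9, b, ses), se = ses)
    m <- fixed_effect_meta(est)
    covered <- covered + (log(m$ci_low) <= b && b <= log(m$ci_high))
  }
  band <- 1.96 * sqrt(0.95 * 0.05 / n_rep)
  expect_lt(abs(covered / n_rep - 0.95), band + 1e-9)
})

test_that("tidy and autoplot expose forest-plot rows", {
  studies <- tibble::tibble(
    cohort = c("a", "b"), hr = c(0.92, 0.97),
    ci_low = c(0.88, 0.93), ci_high = c(0.97, 1.00)
  )
  m <- fixed_effect_meta(studies, snp_id = "rs1")
  td <- tidy(m)
  expect_equal(td$term, c("a", "b", "pooled"))
  expect_equal(td$hr[3], m$pooled_hr)
  expect_s3_class(autoplot(m), "ggplot")
  gl <- glance(m)
  expect_equal(gl$n_studies, 2)
  expect_equal(gl$direction, "--")
})
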