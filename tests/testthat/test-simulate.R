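test_that("haplotype marginals match the specified allele frequencies", {
  h <- simulate_haplotypes(ld_block_spec(1, 0.3), 10000, seed = 1)
  expect_lt(abs(mean(h[, 1]) - 0.3), 0.015)

  maf <- c(0.2, 0.25, 0.3, 0.35, 0.4)
  h2 <- simulate_haplotypes(ld_block_spec(5, maf, adj_r2 = 0.5), 20000,
                            seed = 2)
  expect_true(all(abs(colMeans(h2) - maf) < 0.02))
})

test_that("adjacent-SNP correlation targets sqrt(adj_r2)", {
  h0 <- simulate_haplotypes(ld_block_spec(2, 0.35, adj_r2 = 0), 10000,
                            seed = 3)
  expect_lt(abs(cor(h0[, 1], h0[, 2])), 0.05)

  h8 <- simulate_haplotypes(ld_block_spec(2, 0.35, adj_r2 = 0.8), 20000,
                            seed = 4)
  expect_true(dplyr::between(cor(h8[, 1], h8[, 2])^2, 0.75, 0.85))
})

test_that("infeasible MAF/correlation pairs fail naming the SNP pair", {
  blk <- ld_block_spec(2, c(0.05, 0.5), adj_r2 = 0.81)
  err <- expect_error(simulate_haplotypes(blk, 100, seed = 1),
                      class = "survscan_infeasible_ld")
  expect_match(conditionMessage(err), "1-2")
})

test_that("haplotype pairing produces Hardy-Weinberg hard dosages", {
  zero <- matrix(0L, 10, 2)
  g0 <- genotypes_from_haplotypes(zero, 1)
  expect_true(all(g0$dosage == 0))

  g1 <- genotypes_from_haplotypes(matrix(c(1L, 1L), 2, 1), 1)
  expect_equal(as.vector(g1$dosage), 2)

  expect_error(genotypes_from_haplotypes(matrix(0L, 3, 1), 1),
               class = "survscan_odd_hap")

  h <- simulate_haplotypes(ld_block_spec(1, 0.5), 20000, seed = 5)
  g <- genotypes_from_haplotypes(h, 6)
  counts <- table(factor(g$dosage, levels = 0:2))
  n <- 10000
  exp_counts <- n * c(0.25, 0.5, 0.25)
  sds <- sqrt(n * c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(counts - exp_counts) < 3 * sds))
})

test_that("imputation noise hits the target variance ratio", {
  sim <- make_sim_cohort(n = 10000, n_snps = 2, maf = 0.35, seed = 7)

  ident <- add_imputation_noise(sim$g, 1, seed = 1)
  expect_identical(ident$dosage, sim$g$dosage)

  noisy <- add_imputation_noise(sim$g, 0.9, seed = 2)
  r2 <- snp_info(noisy)$imp_r2
  expect_true(all(dplyr::between(r2, 0.85, 0.95)))
  # stored metadata is the realized ratio of the returned dosages
  d <- noisy$dosage[, 1]
  p <- mean(d) / 2
  expect_equal(r2[1], var(d) / (2 * p * (1 - p)), tolerance = 1e-10)

  # degenerate: monomorphic SNP passes through with missing R2
  mono <- genotype_matrix(matrix(2, 50, 1))
  out <- add_imputation_noise(mono, 0.5, seed = 3)
  expect_equal(var(out$dosage[, 1]), 0)
  expect_true(is.na(snp_info(out)$imp_r2))

  expect_error(add_imputation_noise(noisy, 0.9, seed = 4), "hard dosages")
})

test_that("null survival simulation matches the closed-form Weibull cdf", {
  n <- 5000
  shape <- 1.3
  scale <- 12
  censor <- 10
  blk <- ld_block_spec(1, 0.3)
  g <- genotypes_from_haplotypes(
    simulate_haplotypes(blk, 2 * n, seed = 1), 2, snp_table(blk))
  co <- cohort_spec("null", n, weibull_shape = shape, weibull_scale = scale,
                    admin_censor_time = censor, seed = 9)
  phen <- simulate_survival(g, co, effect_spec(beta_g = 0, beta_age = 0,
                                               beta_sex = 0))
  f_expected <- 1 - exp(-(censor / scale)^shape)
  se <- sqrt(f_expected * (1 - f_expected) / n)
  expect_lt(abs(mean(phen$event) - f_expected), 2 * se)

  # immediate administrative censoring: no events at all
  co0 <- cohort_spec("none", n, admin_censor_time = 1e-9, seed = 9)
  phen0 <- simulate_survival(g, co0, effect_spec())
  expect_equal(sum(phen0$event), 0)
  expect_true(all(phen0$time_years == 1e-9))

  expect_true(all(phen$age >= 55))
})

test_that("Cox CI covers the simulated per-allele effect across seeds", {
  beta_g <- log(2)
  hits <- 0L
  for (s in 1:100) {
    sim <- make_sim_cohort(n = 5000, n_snps = 1, maf = 0.3, beta_g = beta_g,
                           seed = s)
    a <- suppressMessages(scan_snps(sim$g, sim$phen))
    covered <- log(a$ci_low[1]) <= beta_g && beta_g <= log(a$ci_high[1])
    hits <- hits + covered
  }
  expect_gte(hits, 90)
})

test_that("multi-cohort simulation is reproducible and validates names", {
  cohorts <- list(
    cohort_spec("a", 120, seed = 1),
    cohort_spec("b", 80, seed = 2)
  )
  blk <- ld_block_spec(3, 0.3, adj_r2 = 0.5)
  eff <- effect_spec(causal_snp_index = 1, beta_g = 0.2)
  x1 <- simulate_multi_cohort(cohorts, blk, eff, master_seed = 42)
  x2 <- simulate_multi_cohort(cohorts, blk, eff, master_seed = 42)
  expect_identical(x1, x2)
  x3 <- simulate_multi_cohort(cohorts, blk, eff, master_seed = 43)
  expect_false(identical(x1$phen[[1]], x3$phen[[1]]))
  # cohorts get independent genotype draws
  expect_false(identical(x1$geno[[1]]$dosage[1:50, 1],
                         x1$geno[[2]]$dosage[1:50, 1]))

  expect_error(
    simulate_multi_cohort(list(cohort_spec("a", 10), cohort_spec("a", 10)),
                          blk, eff, 1),
    class = "survscan_dup_cohort"
  )
})

test_that("single-cohort path of the multi-cohort simulator matches", {
  blk <- ld_block_spec(2, 0.4)
  eff <- effect_spec()
  co <- cohort_spec("only", 100, seed = 999)
  x <- simulate_multi_cohort(list(co), blk, eff, master_seed = 7)
  h <- simulate_haplotypes(blk, 200, seed = child_seed(7, 1, 1))
  g <- genotypes_from_haplotypes(h, child_seed(7, 1, 2), snp_table(blk))
  co$seed <- child_seed(7, 1, 3)
  expect_identical(x$geno[[1]]$dosage, g$dosage)
  expect_identical(x$phen[[1]], simulate_survival(g, co, eff))
})
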