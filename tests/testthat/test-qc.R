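test_that("HWE chi-square handles exact-fit, monomorphic and deficit cases", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chisq, 0)
  expect_equal(perfect$p, 1)

  mono <- hwe_test(100, 0, 0)
  expect_equal(mono$chisq, 0)
  expect_equal(mono$p, 1)

  # heterozygote deficit at n = 100: expected counts (20.25, 49.5, 30.25)
  deficit <- hwe_test(30, 30, 40)
  expected <- 100 * c(0.45^2, 2 * 0.45 * 0.55, 0.55^2)
  expect_equal(expected, c(20.25, 49.5, 30.25))
  expect_equal(deficit$chisq,
               sum((c(30, 30, 40) - expected)^2 / expected))
  expect_lt(deficit$p, 1e-4)

  expect_error(hwe_test(0, 0, 0), class = "survscan_empty_counts")
})

test_that("chi-square and exact HWE tests agree where the chi-square applies", {
  # Exhaustive sweep of genotype-count triples with n <= 50, restricted to
  # the chi-square's classical applicability region (all HWE-expected
  # counts >= 5): there the two tests can only differ on pass/fail at 1e-4
  # when both p-values sit in the immediate neighbourhood of the threshold,
  # so outside an order-of-magnitude band around 1e-4 the verdicts must be
  # identical. (Outside that region — e.g. a lone rare homozygote — the
  # asymptotic tail is simply wrong and no agreement can be promised.)
  triples <- do.call(rbind, lapply(1:50, function(n) {
    g <- expand.grid(a = 0:n, h = 0:n)
    g <- g[g$a + g$h <= n, ]
    g$b <- n - g$a - g$h
    g
  }))
  n <- triples$a + triples$h + triples$b
  p <- (2 * triples$b + triples$h) / (2 * n)
  min_expected <- pmin(n * p^2, n * 2 * p * (1 - p), n * (1 - p)^2)
  triples <- triples[min_expected >= 5, ]
  p_exact <- mapply(hwe_exact_p, triples$a, triples$h, triples$b)
  p_chisq <- hwe_test(triples$a, triples$h, triples$b)$p
  away <- p_exact > 1e-3 | p_exact < 1e-5
  expect_gt(sum(away), 5000)
  expect_identical((p_chisq >= 1e-4)[away], (p_exact >= 1e-4)[away])
})

test_that("snp_summary computes frequency, call rate and hard-call counts", {
  d <- matrix(c(0, 1, 2, 1,
                2, 2, NA, 2), nrow = 4,
              dimnames = list(NULL, c("s1", "s2")))
  g <- genotype_matrix(d)
  s <- snp_summary(g)
  expect_equal(s$coded_freq, c(0.5, 1))
  expect_equal(s$call_rate, c(1, 0.75))
  expect_equal(s$maf, c(0.5, 0))
  expect_equal(s$n_het[1], 2)

  sim <- make_sim_cohort(n = 10000, n_snps = 1, maf = 0.35, seed = 21)
  ss <- snp_summary(sim$g)
  expect_lt(abs(ss$maf - 0.35), 0.01)

  # HWE is skipped for poorly imputed SNPs
  low <- sim$g
  low$snps$imp_r2 <- 0.2
  expect_true(is.na(snp_summary(low)$hwe_p))
})

test_that("QC boundary conventions follow the stated inequalities", {
  mk <- function(maf = 0.3, call_rate = 1, imp_r2 = 0.95, hwe_p = 0.5) {
    tibble::tibble(snp_id = "s", maf = maf, call_rate = call_rate,
                   imp_r2 = imp_r2, hwe_p = hwe_p)
  }
  # MAF exactly at the bound fails (strict >)
  expect_false(apply_qc(mk(maf = 0.05))$pass)
  expect_true(apply_qc(mk(maf = 0.0501))$pass)
  # call rate exactly at the bound passes (inclusive >=)
  expect_true(apply_qc(mk(call_rate = 0.95))$pass)
  expect_false(apply_qc(mk(call_rate = 0.9499))$pass)
  # imputation R2 at the bound fails (strict >)
  expect_false(apply_qc(mk(imp_r2 = 0.8))$pass)
  # HWE p at the bound passes (inclusive >=)
  expect_true(apply_qc(mk(hwe_p = 1e-4))$pass)
  expect_false(apply_qc(mk(hwe_p = 0.9e-4))$pass)
  # missing metadata cannot fail a criterion
  expect_true(apply_qc(mk(imp_r2 = NA, hwe_p = NA))$pass)
  # everything-at-zero thresholds: any polymorphic SNP passes
  loose <- qc_thresholds(0, 0, 0, 0)
  expect_true(apply_qc(mk(maf = 0.01, call_rate = 0.5, imp_r2 = 0.1,
                          hwe_p = 1e-10), loose)$pass)
})

test_that("QC filtering is monotone in every threshold", {
  set.seed(31)
  tab <- tibble::tibble(
    snp_id = sprintf("s%03d", 1:200),
    maf = runif(200, 0, 0.5),
    call_rate = runif(200, 0.8, 1),
    imp_r2 = runif(200, 0.3, 1),
    hwe_p = runif(200)^3
  )
  base <- qc_thresholds()
  passed <- apply_qc(tab, base)$pass
  tighter <- list(
    qc_thresholds(hwe_p_min = 1e-2),
    qc_thresholds(call_rate_min = 0.99),
    qc_thresholds(imp_r2_min = 0.9),
    qc_thresholds(maf_min = 0.2)
  )
  for (thr in tighter) {
    expect_true(all(apply_qc(tab, thr)$pass <= passed))
  }
  rep <- qc_report(apply_qc(tab, base))
  expect_equal(rep$n_snps, 200)
  expect_lte(rep$pass, 200)
})

test_that("gene windows expand, merge and collect SNPs", {
  # two genes 150 kb apart: expanded 100 kb windows overlap -> one region
  genes <- tibble::tibble(
    gene = c("g1", "g2"), chrom = "6",
    start = c(1e6, 1e6 + 160000), end = c(1e6 + 10000, 1e6 + 170000)
  )
  snps <- tibble::tibble(snp_id = "rs1", chrom = "6", pos = 1e6 + 80000)
  merged <- build_rois(genes, snps)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$genes[[1]], c("g1", "g2"))

  # 250 kb apart: windows do not overlap -> two regions
  genes2 <- dplyr::mutate(genes, start = c(1e6, 1e6 + 260000),
                          end = c(1e6 + 10000, 1e6 + 270000))
  expect_equal(nrow(build_rois(genes2, snps)), 2)

  # merged windows are disjoint per chromosome
  set.seed(41)
  many <- tibble::tibble(
    gene = sprintf("g%02d", 1:12), chrom = rep(c("6", "11"), each = 6),
    start = round(runif(12, 1e6, 5e6))
  )
  many$end <- many$start + 20000
  rois <- build_rois(many, snps)
  for (chr in unique(rois$chrom)) {
    w <- dplyr::arrange(rois[rois$chrom == chr, ], start)
    if (nrow(w) > 1) expect_true(all(w$start[-1] > w$end[-nrow(w)]))
  }

  expect_error(
    build_rois(tibble::tibble(gene = "bad", chrom = "1", start = 10,
                              end = 5), snps),
    class = "survscan_bad_gene"
  )
})

test_that("three adjacent genes merge into one region holding 148 SNPs", {
  genes <- tibble::tibble(
    gene = c("hspA", "hspB", "hspC"), chrom = "6",
    start = c(31.78e6, 31.795e6, 31.83e6),
    end = c(31.785e6, 31.8e6, 31.84e6)
  )
  snps <- tibble::tibble(
    snp_id = sprintf("rs%03d", 1:148), chrom = "6",
    pos = as.integer(seq(31.69e6, 31.93e6, length.out = 148))
  )
  rois <- build_rois(genes, snps)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$n_snps, 148)
  expect_equal(rois$genes[[1]], c("hspA", "hspB", "hspC"))
})
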