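#' Simulate LD-structured haplotypes
#'
#' Draws binary haplotypes from a first-order Markov chain along the block:
#' the first SNP is Bernoulli(`maf[1]`) and each subsequent allele is drawn
#' conditionally on its left neighbour so that the correlation of adjacent
#' alleles equals `sqrt(adj_r2)` and the marginal frequency equals the
#' specified MAF. The chain gives geometrically decaying LD with distance —
#' correlated tests for the max-T correction to work on, nothing more.
#'
#' Not every (MAF pair, correlation) combination is achievable for binary
#' variables: the joint probability of two coded alleles is capped by the
#' Frechet bound `min(p1, p2)`. Infeasible requests fail, naming the pair.
#'
#' @param block An [ld_block_spec()].
#' @param n_hap Number of haplotypes (even, at least 2).
#' @param seed Integer seed.
#' @return Integer matrix `n_hap` x `n_snps` with entries in \{0, 1\}.
#' @export
#' @examples
#' h <- simulate_haplotypes(ld_block_spec(3, 0.3, adj_r2 = 0.5), 200, seed = 1)
#' colMeans(h)
simulate_haplotypes <- function(block, n_hap, seed) {
  stopifnot(inherits(block, "ld_block_spec"))
  if (!is_count(n_hap) || n_hap < 2 || n_hap %% 2 != 0) {
    stop("`n_hap` must be an even count >= 2")
  }
  maf <- block$maf
  r <- sqrt(block$adj_r2)
  m <- block$n_snps
  set.seed(seed)
  h <- matrix(0L, nrow = n_hap, ncol = m)
  h[, 1] <- rbinom(n_hap, 1, maf[1])
  if (m > 1) {
    for (j in 2:m) {
      p1 <- maf[j - 1]
      p2 <- maf[j]
      p11 <- p1 * p2 + r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
      if (p11 > min(p1, p2) + 1e-12) {
        abort_survscan(
          sprintf(paste0(
            "adjacent correlation sqrt(%.3g) is infeasible for SNP pair ",
            "%d-%d (maf %.3g, %.3g): joint allele probability %.4g exceeds ",
            "the Frechet bound %.4g"),
            block$adj_r2, j - 1, j, p1, p2, p11, min(p1, p2)),
          "survscan_infeasible_ld"
        )
      }
      p_given1 <- p11 / p1
      p_given0 <- (p2 - p11) / (1 - p1)
      h[, j] <- rbinom(n_hap, 1, ifelse(h[, j - 1] == 1, p_given1, p_given0))
    }
  }
  colnames(h) <- sprintf("snp_%03d", seq_len(m))
  h
}

#' SNP annotation table for a simulated LD block
#'
#' @param block An [ld_block_spec()].
#' @return A tibble with `snp_id`, `chrom`, `pos`, `gene`, `coded_allele`,
#'   `noncoded_allele`, `imp_r2` (the latter `NA` until
#'   [add_imputation_noise()] is applied).
#' @export
snp_table <- function(block) {
  stopifnot(inherits(block, "ld_block_spec"))
  tibble::tibble(
    snp_id = sprintf("snp_%03d", seq_len(block$n_snps)),
    chrom = block$chrom,
    pos = block$positions,
    gene = block$gene_label,
    coded_allele = "A",
    noncoded_allele = "G",
    imp_r2 = NA_real_
  )
}

#' Pair haplotypes into diploid genotype dosages
#'
#' Randomly pairs haplotypes and sums each pair into a hard dosage in
#' \{0, 1, 2\}; under random pairing Hardy-Weinberg proportions hold in
#' expectation.
#'
#' @param haplotypes Binary haplotype matrix with an even number of rows.
#' @param pairing_seed Integer seed for the random pairing.
#' @param snps Optional SNP annotation (e.g. [snp_table()]) to attach.
#' @return A [genotype_matrix()] of hard dosages.
#' @export
genotypes_from_haplotypes <- function(haplotypes, pairing_seed, snps = NULL) {
  stopifnot(is.matrix(haplotypes))
  n_hap <- nrow(haplotypes)
  if (n_hap %% 2 != 0) {
    abort_survscan("number of haplotypes must be even", "survscan_odd_hap")
  }
  set.seed(pairing_seed)
  perm <- sample.int(n_hap)
  a <- haplotypes[perm[seq(1, n_hap, by = 2)], , drop = FALSE]
  b <- haplotypes[perm[seq(2, n_hap, by = 2)], , drop = FALSE]
  dosage <- a + b
  storage.mode(dosage) <- "double"
  rownames(dosage) <- sprintf("ind_%05d", seq_len(n_hap / 2))
  genotype_matrix(dosage, snps)
}

#' Blur hard genotypes into imputed dosages with a target quality R-squared
#'
#' Imputation quality is summarized by R-squared, the ratio of the variance
#' of imputed dosages to the binomial variance `2 p (1 - p)`. The blur is a
#' linear shrink of the hard dosage toward the SNP mean plus Gaussian jitter,
#' then clipping to \[0, 2\]: writing `v = var(g)`, the output is
#' `mean(g) + r2 * (g - mean(g)) + e` with `e ~ N(0, r2 (1 - r2) v)`, so that
#' the output variance is `r2 * v` and the output has regression slope 1 on
#' the truth — the two properties a conditional-expectation dosage has.
#' Clipping removes tail variance, so the shrink factor is recalibrated by a
#' short fixed-point iteration until the post-clip variance ratio matches
#' the target (within 0.01). The per-SNP `imp_r2` stored in the annotation
#' is the *realized* variance ratio of the returned dosages, not the target.
#'
#' @param g A [genotype_matrix()] of hard dosages in \{0, 1, 2\}.
#' @param target_r2 Target R-squared in (0, 1\]; scalar or one per SNP.
#' @param seed Integer seed.
#' @return A `genotype_matrix` of fractional dosages with updated `imp_r2`.
#'   Monomorphic SNPs pass through untouched with `imp_r2 = NA`.
#' @export
add_imputation_noise <- function(g, target_r2, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  ok <- is.na(d) | d %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("`add_imputation_noise()` expects hard dosages in {0, 1, 2}")
  }
  m <- ncol(d)
  if (length(target_r2) == 1) target_r2 <- rep(target_r2, m)
  stopifnot(length(target_r2) == m, all(target_r2 > 0), all(target_r2 <= 1))
  set.seed(seed)
  out <- d
  realized <- rep(NA_real_, m)
  ratio_of <- function(y) {
    p_hat <- mean(y) / 2
    denom <- 2 * p_hat * (1 - p_hat)
    if (denom > 0) var(y) / denom else NA_real_
  }
  for (j in seq_len(m)) {
    x <- d[, j]
    obs <- !is.na(x)
    v <- var(x[obs])
    if (!is.finite(v) || v == 0) next # monomorphic: zero variance in and out
    r2 <- target_r2[j]
    if (r2 < 1) {
      mu <- mean(x[obs])
      z <- rnorm(sum(obs))
      construct <- function(shrink) {
        e <- z * sqrt(shrink * (1 - shrink) * v)
        pmin(pmax(mu + shrink * (x[obs] - mu) + e, 0), 2)
      }
      # post-clip variance ratio rises monotonically with the shrink factor,
      # so bisect it until the realized ratio matches the target
      lo <- 0
      hi <- 1
      shrink <- r2
      for (it in 1:30) {
        y <- construct(shrink)
        got <- ratio_of(y)
        if (!is.finite(got) || abs(got - r2) < 0.005) break
        if (got < r2) lo <- shrink else hi <- shrink
        shrink <- (lo + hi) / 2
      }
      out[obs, j] <- y
    }
    realized[j] <- ratio_of(out[obs, j])
  }
  snps <- g$snps
  snps$imp_r2 <- realized
  genotype_matrix(out, snps)
}

#' Simulate survival phenotypes under a Weibull proportional-hazards model
#'
#' Baseline age is Normal truncated below at 55 years; sex is
#' Bernoulli(`frac_female`). The event time solves
#' `T = lambda * (-log(U) / exp(lp))^(1/rho)` with
#' `lp = beta_g * dosage + beta_age * (age - age_mean) + beta_sex * sex`,
#' and observation stops at the administrative censoring time. The time
#' scale is time-on-study (follow-up years) with age as a covariate, which
#' is the model the downstream Cox scan fits.
#'
#' @param g A [genotype_matrix()] supplying the causal dosage (and the
#'   cohort size).
#' @param cohort A [cohort_spec()].
#' @param effects An [effect_spec()].
#' @return A phenotype tibble: `iid`, `time_years`, `event`, `age`, `sex`.
#' @export
#' @examples
#' blk <- ld_block_spec(1, 0.3)
#' g <- genotypes_from_haplotypes(
#'   simulate_haplotypes(blk, 400, seed = 1), 2, snp_table(blk))
#' phen <- simulate_survival(g, cohort_spec("a", 200, seed = 3), effect_spec())
#' mean(phen$event)
simulate_survival <- function(g, cohort, effects) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cohort, "cohort_spec"),
            inherits(effects, "effect_spec"))
  n <- nrow(g$dosage)
  if (n != cohort$n) {
    stop("genotype matrix has ", n, " individuals but cohort$n is ", cohort$n)
  }
  set.seed(cohort$seed)
  lo <- pnorm(55, cohort$age_mean, cohort$age_sd)
  age <- qnorm(runif(n, lo, 1), cohort$age_mean, cohort$age_sd)
  sex <- rbinom(n, 1, cohort$frac_female)
  dose <- if (is.null(effects$causal_snp_index)) {
    rep(0, n)
  } else {
    if (effects$causal_snp_index > ncol(g$dosage)) {
      stop("causal_snp_index exceeds the number of SNPs")
    }
    d <- g$dosage[, effects$causal_snp_index]
    ifelse(is.na(d), mean(d, na.rm = TRUE), d)
  }
  lp <- effects$beta_g * dose +
    effects$beta_age * (age - cohort$age_mean) +
    effects$beta_sex * sex
  u <- runif(n)
  t_event <- cohort$weibull_scale * (-log(u) / exp(lp))^(1 / cohort$weibull_shape)
  time <- pmin(t_event, cohort$admin_censor_time)
  tibble::tibble(
    iid = rownames(g$dosage),
    time_years = time,
    event = as.integer(t_event <= cohort$admin_censor_time),
    age = age,
    sex = as.integer(sex)
  )
}

#' Simulate several cohorts sharing one LD block and one true effect
#'
#' Cohorts share the LD structure and effect sizes but get independent
#' genotype and phenotype draws; all per-cohort, per-stage seeds are derived
#' from `master_seed` through [child_seed()], so the same master seed gives
#' bit-identical output.
#'
#' @param cohorts List of [cohort_spec()]s with unique names.
#' @param block An [ld_block_spec()].
#' @param effects An [effect_spec()].
#' @param master_seed Integer master seed (overrides the per-cohort seeds).
#' @param imp_r2 Optional target imputation R-squared passed to
#'   [add_imputation_noise()] for every cohort; `NULL` keeps hard dosages.
#' @return A tibble with one row per cohort and list-columns `geno`
#'   (genotype matrices) and `phen` (phenotype tibbles).
#' @export
simulate_multi_cohort <- function(cohorts, block, effects, master_seed,
                                  imp_r2 = NULL) {
  stopifnot(length(cohorts) >= 1)
  nm <- vapply(cohorts, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort_survscan("duplicate cohort names", "survscan_dup_cohort")
  }
  snps <- snp_table(block)
  rows <- purrr::imap(cohorts, function(cohort, key) {
    i <- match(cohort$name, nm)
    hap <- simulate_haplotypes(block, 2 * cohort$n,
                               seed = child_seed(master_seed, i, 1))
    g <- genotypes_from_haplotypes(hap, child_seed(master_seed, i, 2), snps)
    if (!is.null(imp_r2)) {
      g <- add_imputation_noise(g, imp_r2, child_seed(master_seed, i, 4))
    }
    cohort$seed <- child_seed(master_seed, i, 3)
    phen <- simulate_survival(g, cohort, effects)
    tibble::tibble(cohort = cohort$name, geno = list(g), phen = list(phen))
  })
  dplyr::bind_rows(rows)
}
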