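#' Configuration for region-wide max-statistic permutation
#'
#' @param n_perm Number of permutation replicates B (default 10,000).
#' @param suggestive_threshold Region-level empirical p below which a region
#'   is flagged suggestive (strict `<`; default 0.10).
#' @param seed Integer seed; each replicate's permutation is drawn from a
#'   child seed ([child_seed()]) so replicates are independently
#'   reproducible.
#' @param estimator `"ratio"` computes the empirical p as r/B, the plain
#'   proportion of null maxima at or above the observed statistic (it can
#'   return 0); `"add_one"` uses (r+1)/(B+1).
#' @return An object of class `perm_config`.
#' @export
perm_config <- function(n_perm = 10000, suggestive_threshold = 0.10,
                        seed = 1L, estimator = c("ratio", "add_one")) {
  stopifnot(is_count(n_perm), n_perm >= 1)
  stopifnot(suggestive_threshold > 0, suggestive_threshold < 1)
  structure(
    list(n_perm = as.integer(n_perm),
         suggestive_threshold = suggestive_threshold,
         seed = as.integer(seed), estimator = match.arg(estimator)),
    class = "perm_config"
  )
}

#' Permute phenotypes against fixed genotypes
#'
#' Reallocates the phenotype tuples `(time_years, event, age, sex)` uniformly
#' at random across individuals, leaving each individual's genotypes (and the
#' `iid` order) fixed. Permuting whole tuples preserves the outcome-covariate
#' relationship and the LD between SNPs; only the genotype-phenotype link is
#' broken, which is exactly the null the region-wide max statistic needs.
#'
#' @param phen A phenotype tibble.
#' @param seed Integer seed.
#' @return The phenotype tibble with tuples permuted.
#' @export
permute_phenotypes <- function(phen, seed) {
  set.seed(seed)
  p <- sample.int(nrow(phen))
  cols <- c("time_years", "event", "age", "sex")
  phen[, cols] <- phen[p, cols]
  phen
}

#' Null distribution of the region-wide maximum statistic
#'
#' For each of B replicates, re-runs the per-SNP Cox scan over all region
#' SNPs on phenotypes permuted as intact tuples and records the maximum Wald
#' chi-square. All SNPs share one permutation per replicate — the joint null
#' that makes the max-T correction valid. A SNP whose fit fails in a
#' replicate contributes nothing to that replicate's maximum (failure count
#' attached as an attribute).
#'
#' Internally the engine permutes genotype rows by the inverse permutation
#' instead of materializing a permuted phenotype table: the set of
#' (genotype, phenotype) pairs — and hence every statistic — is identical,
#' and the phenotype ordering can be reused across all B x m fits.
#'
#' @param g A [genotype_matrix()].
#' @param phen A phenotype tibble.
#' @param snp_ids Region SNPs (default: all).
#' @param config A [perm_config()].
#' @param min_age Baseline age eligibility (default 55).
#' @return Numeric vector of B null maxima, with attribute `n_failed_fits`.
#' @export
roi_null_maxima <- function(g, phen, snp_ids = NULL, config = perm_config(),
                            min_age = 55) {
  stopifnot(inherits(config, "perm_config"))
  al <- align_cohort(g, phen)
  g <- al$g
  phen <- al$phen
  keep <- !is.na(phen$age) & phen$age >= min_age
  phen <- phen[keep, ]
  d <- g$dosage[keep, , drop = FALSE]
  if (is.null(snp_ids)) snp_ids <- colnames(d)
  stopifnot(length(snp_ids) >= 1)
  d <- d[, snp_ids, drop = FALSE]
  n <- nrow(d)
  m <- ncol(d)
  usable <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  if (!any(usable)) {
    abort_survscan("all region SNPs are constant", "survscan_constant_roi")
  }
  B <- config$n_perm
  ctrl <- survival::coxph.control()
  maxima <- rep(-Inf, B)
  n_failed <- 0L
  complete <- !anyNA(d)
  if (complete) {
    # fast path: phenotype pre-sorted by time, genotype rows permuted
    o <- order(phen$time_years)
    y <- survival::Surv(phen$time_years[o], phen$event[o])
    age_s <- phen$age[o]
    sex_s <- phen$sex[o]
    for (b in seq_len(B)) {
      set.seed(child_seed(config$seed, b, 10))
      p <- sample.int(n)
      idx <- inv_perm(p)[o]
      best <- -Inf
      for (j in which(usable)) {
        x <- cbind(d[idx, j], age_s, sex_s)
        f <- cox_fit_raw(x, y, ctrl)
        if (f$converged) {
          best <- max(best, (f$beta / f$se)^2)
        } else {
          n_failed <- n_failed + 1L
        }
      }
      maxima[b] <- best
    }
  } else {
    for (b in seq_len(B)) {
      pp <- permute_phenotypes(phen, child_seed(config$seed, b, 10))
      best <- -Inf
      for (j in which(usable)) {
        obs <- !is.na(d[, j])
        x <- cbind(d[obs, j], pp$age[obs], pp$sex[obs])
        y <- survival::Surv(pp$time_years[obs], pp$event[obs])
        f <- cox_fit_raw(x, y, ctrl)
        if (f$converged) {
          best <- max(best, (f$beta / f$se)^2)
        } else {
          n_failed <- n_failed + 1L
        }
      }
      maxima[b] <- best
    }
  }
  maxima[!is.finite(maxima)] <- NA_real_
  attr(maxima, "n_failed_fits") <- n_failed
  maxima
}

#' Empirical p-value against a permutation null sample
#'
#' The proportion of null (region-maximum) statistics greater than or equal
#' to the observed statistic: r/B, ties counted as exceedances. With the
#' default `"ratio"` estimator the value can be exactly 0 when the observed
#' statistic beats every replicate.
#'
#' @param observed Observed statistic(s); vectorized.
#' @param null_maxima Numeric vector of null maxima.
#' @param estimator `"ratio"` (r/B) or `"add_one"` ((r+1)/(B+1)).
#' @return Empirical p-value(s) in \[0, 1\].
#' @export
#' @examples
#' empirical_p(3, c(1, 2, 3, 4))  # ties count: 2/4
empirical_p <- function(observed, null_maxima,
                        estimator = c("ratio", "add_one")) {
  estimator <- match.arg(estimator)
  nm <- null_maxima[!is.na(null_maxima)]
  B <- length(nm)
  stopifnot(B >= 1)
  vapply(observed, function(s) {
    if (is.na(s)) return(NA_real_)
    r <- sum(nm >= s)
    if (estimator == "ratio") r / B else (r + 1) / (B + 1)
  }, double(1))
}

#' Region-wide max-T permutation test
#'
#' Runs the observed per-SNP Cox scan over a region, draws the null
#' distribution of the region-wide maximum Wald statistic by phenotype
#' permutation, and converts every observed statistic into a family-wise
#' empirical p-value. The region-level empirical p is the minimum over SNPs
#' (equivalently the empirical p of the observed maximum), and the region is
#' flagged suggestive when it falls strictly below the configured threshold.
#'
#' @param g A [genotype_matrix()].
#' @param phen A phenotype tibble.
#' @param snp_ids Region SNPs (default: all in `g`).
#' @param config A [perm_config()].
#' @param roi_id Region label.
#' @param cohort Cohort label for the observed scan.
#' @param min_age Baseline age eligibility (default 55).
#' @return An object of class `perm_result`; see [tidy.perm_result()] and
#'   [glance.perm_result()].
#' @export
roi_permutation <- function(g, phen, snp_ids = NULL, config = perm_config(),
                            roi_id = "roi", cohort = "cohort",
                            min_age = 55) {
  if (is.null(snp_ids)) snp_ids <- colnames(g$dosage)
  observed <- scan_snps(g, phen, snp_ids, cohort = cohort, min_age = min_age)
  maxima <- roi_null_maxima(g, phen, snp_ids, config, min_age = min_age)
  emp <- empirical_p(observed$stat, maxima, estimator = config$estimator)
  roi_emp_p <- suppressWarnings(min(emp, na.rm = TRUE))
  if (!is.finite(roi_emp_p)) roi_emp_p <- NA_real_
  structure(
    list(
      roi_id = roi_id,
      observed = observed,
      null_maxima = as.numeric(maxima),
      emp_p = emp,
      roi_emp_p = roi_emp_p,
      suggestive = isTRUE(roi_emp_p < config$suggestive_threshold),
      config = config,
      n_failed_fits = attr(maxima, "n_failed_fits")
    ),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> region '", x$roi_id, "': ", nrow(x$observed),
      " SNPs, B = ", length(x$null_maxima), "\n", sep = "")
  cat("  region empirical p = ", format(x$roi_emp_p),
      if (x$suggestive) "  (suggestive)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a max-T permutation result
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return One row per SNP: observed statistic, nominal Wald p, family-wise
#'   empirical p.
#' @export
tidy.perm_result <- function(x, ...) {
  tibble::tibble(
    roi_id = x$roi_id,
    snp_id = x$observed$snp_id,
    stat = x$observed$stat,
    p = x$observed$p,
    emp_p = x$emp_p
  )
}

#' One-row summary of a max-T permutation result
#' @param x A `perm_result`.
#' @param ... Unused.
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(
    roi_id = x$roi_id,
    n_snps = nrow(x$observed),
    n_perm = length(x$null_maxima),
    roi_emp_p = x$roi_emp_p,
    suggestive = x$suggestive,
    n_failed_fits = x$n_failed_fits
  )
}

#' Flag suggestive regions
#'
#' @param perm_results A list of `perm_result` objects (or a single one).
#' @param threshold Strict upper bound on the region empirical p
#'   (default 0.10).
#' @return A tibble of suggestive regions ordered by `roi_emp_p`.
#' @export
flag_suggestive <- function(perm_results, threshold = 0.10) {
  if (inherits(perm_results, "perm_result")) {
    perm_results <- list(perm_results)
  }
  if (length(perm_results) == 0) {
    return(tibble::tibble(roi_id = character(), n_snps = integer(),
                          n_perm = integer(), roi_emp_p = double(),
                          suggestive = logical(), n_failed_fits = integer()))
  }
  tab <- purrr::map_dfr(perm_results, glance)
  tab <- tab[!is.na(tab$roi_emp_p) & tab$roi_emp_p < threshold, ]
  dplyr::arrange(tab, .data$roi_emp_p)
}
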