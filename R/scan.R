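#' Additive Cox proportional-hazards fit for one SNP
#'
#' Maximizes the Cox partial likelihood (Efron ties) for
#' `Surv(time, event) ~ dosage + age + sex` on the time-on-study scale and
#' reports the dosage coefficient: the log hazard ratio per additional coded
#' allele, its standard error, Wald chi-square (1 df), two-sided p, and the
#' HR with 95% CI. Individuals missing any used variable are excluded
#' (per-SNP complete case). Covariates other than dosage that are constant
#' among complete cases carry no information in a partial likelihood and are
#' dropped from the design.
#'
#' @param time Follow-up time in years.
#' @param event Event indicator (1 = died).
#' @param dosage Coded-allele dosage in \[0, 2\].
#' @param age,sex Adjustment covariates; pass `NULL` to omit.
#' @param snp_id,cohort Labels carried into the result row.
#' @param min_events Minimum number of events required (default 2).
#' @return A one-row tibble: `snp_id`, `cohort`, `n`, `n_events`, `beta`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `stat`, `p`, `status`. A fit that does
#'   not converge returns `status = "nonconverged"` with `NA` estimates —
#'   never a silent NaN.
#' @export
#' @examples
#' set.seed(1)
#' n <- 200
#' d <- rbinom(n, 2, 0.3)
#' t <- rexp(n, exp(0.5 * d) / 10)
#' cox_fit(pmin(t, 12), as.integer(t <= 12), d,
#'         age = rnorm(n, 70, 5), sex = rbinom(n, 1, 0.5))
cox_fit <- function(time, event, dosage, age = NULL, sex = NULL,
                    snp_id = NA_character_, cohort = NA_character_,
                    min_events = 2) {
  df <- cbind(time, event, dosage,
              if (!is.null(age)) age, if (!is.null(sex)) sex)
  keep <- complete.cases(df)
  time <- time[keep]; event <- event[keep]; dosage <- dosage[keep]
  if (!is.null(age)) age <- age[keep]
  if (!is.null(sex)) sex <- sex[keep]
  n <- length(time)
  n_events <- sum(event)
  base <- tibble::tibble(
    snp_id = snp_id, cohort = cohort, n = n, n_events = n_events,
    beta = NA_real_, se = NA_real_, hr = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_,
    stat = NA_real_, p = NA_real_, status = "ok"
  )
  if (n_events < min_events) {
    stop("need at least ", min_events, " events, got ", n_events)
  }
  if (length(unique(dosage)) < 2) {
    abort_survscan("dosage is constant among complete cases",
                   "survscan_constant_covariate")
  }
  x <- cbind(dosage = dosage)
  if (!is.null(age) && length(unique(age)) > 1) x <- cbind(x, age = age)
  if (!is.null(sex) && length(unique(sex)) > 1) x <- cbind(x, sex = sex)
  fit <- cox_fit_raw(x, survival::Surv(time, event))
  if (!fit$converged) {
    base$status <- "nonconverged"
    return(base)
  }
  assoc_row(base, fit$beta, fit$se)
}

# fill the estimate columns of an AssocResult row from (beta, se)
assoc_row <- function(base, beta, se) {
  base$beta <- beta
  base$se <- se
  base$hr <- exp(beta)
  base$ci_low <- exp(beta - z975 * se)
  base$ci_high <- exp(beta + z975 * se)
  base$stat <- (beta / se)^2
  base$p <- pchisq(base$stat, df = 1, lower.tail = FALSE)
  base
}

# thin, fast wrapper around survival's workhorse partial-likelihood fitter;
# returns the first-column coefficient and a convergence verdict
cox_fit_raw <- function(x, y, ctrl = survival::coxph.control()) {
  storage.mode(x) <- "double"
  f <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = ctrl, weights = NULL, method = "efron",
                          rownames = NULL, resid = FALSE)
    ),
    error = function(e) NULL
  )
  if (is.null(f)) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  }
  beta <- f$coefficients[1]
  v <- f$var[1, 1]
  bad <- !is.finite(beta) || !is.finite(v) || v <= 0 ||
    abs(beta) > 15 || f$iter >= ctrl$iter.max
  list(beta = unname(beta), se = sqrt(v), converged = !bad)
}

#' Per-SNP Cox association scan over a genotype matrix
#'
#' Runs [cox_fit()] for every requested SNP against the same phenotype
#' table, after aligning individuals by id and excluding those younger than
#' `min_age` at baseline (the analysis eligibility age; the exclusion count
#' is messaged). SNPs that cannot be fit are kept as rows with a
#' diagnostic `status` (`"constant_dosage"`, `"too_few_events"`,
#' `"nonconverged"`) rather than dropped. Output order follows `snp_ids`;
#' the scan is deterministic.
#'
#' @param g A [genotype_matrix()].
#' @param phen A phenotype tibble (`iid, time_years, event, age, sex`).
#' @param snp_ids SNPs to scan (default: all columns of `g`).
#' @param cohort Cohort label for the result rows.
#' @param min_age Baseline age eligibility in years (default 55);
#'   `-Inf` disables.
#' @param adjust Adjust for age and sex (default TRUE).
#' @return An association tibble, one row per SNP, with `coded_allele` and
#'   `coded_freq` taken from the genotype annotation and observed dosages.
#' @export
scan_snps <- function(g, phen, snp_ids = NULL, cohort = "cohort",
                      min_age = 55, adjust = TRUE) {
  al <- align_cohort(g, phen)
  g <- al$g
  phen <- al$phen
  young <- phen$age < min_age
  if (any(young, na.rm = TRUE)) {
    message(sum(young, na.rm = TRUE),
            " individual(s) below baseline age ", min_age, " excluded")
    keep <- !is.na(young) & !young
    phen <- phen[keep, ]
    g <- genotype_matrix(g$dosage[keep, , drop = FALSE], g$snps)
  }
  if (is.null(snp_ids)) snp_ids <- colnames(g$dosage)
  if (length(snp_ids) == 0) {
    return(tibble::tibble(
      snp_id = character(), cohort = character(), coded_allele = character(),
      coded_freq = double(), n = integer(), n_events = integer(),
      beta = double(), se = double(), hr = double(), ci_low = double(),
      ci_high = double(), stat = double(), p = double(), status = character()
    ))
  }
  info <- g$snps[match(snp_ids, g$snps$snp_id), ]
  rows <- purrr::map(seq_along(snp_ids), function(k) {
    j <- match(snp_ids[k], colnames(g$dosage))
    dose <- g$dosage[, j]
    row <- tryCatch(
      cox_fit(phen$time_years, phen$event, dose,
              age = if (adjust) phen$age, sex = if (adjust) phen$sex,
              snp_id = snp_ids[k], cohort = cohort),
      survscan_constant_covariate = function(e) {
        failed_row(snp_ids[k], cohort, dose, phen, "constant_dosage")
      },
      error = function(e) {
        failed_row(snp_ids[k], cohort, dose, phen, "too_few_events")
      }
    )
    row$coded_allele <- info$coded_allele[k]
    row$coded_freq <- mean(dose, na.rm = TRUE) / 2
    row
  })
  out <- dplyr::bind_rows(rows)
  n_failed <- sum(out$status != "ok")
  if (n_failed > 0) {
    message(n_failed, " SNP(s) could not be fit (see `status` column)")
  }
  dplyr::relocate(out, "coded_allele", "coded_freq", .after = "cohort")
}

failed_row <- function(snp_id, cohort, dose, phen, status) {
  keep <- !is.na(dose)
  tibble::tibble(
    snp_id = snp_id, cohort = cohort,
    n = sum(keep), n_events = sum(phen$event[keep], na.rm = TRUE),
    beta = NA_real_, se = NA_real_, hr = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, stat = NA_real_, p = NA_real_,
    status = status
  )
}
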