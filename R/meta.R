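#' Standard error of a log hazard ratio from a printed confidence interval
#'
#' Published tables report HR and 95% CI; inverse-variance pooling needs the
#' standard error of the log HR. For a Wald interval,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param ci_low,ci_high 95% CI bounds on the HR scale (positive).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return The standard error(s) of the log HR.
#' @export
#' @examples
#' se_from_ci(0.88, 0.97)
se_from_ci <- function(ci_low, ci_high, conf_level = 0.95) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    abort_survscan("CI bounds must be positive", "survscan_bad_ci")
  }
  if (any(ci_high < ci_low)) {
    abort_survscan("ci_high must be >= ci_low", "survscan_bad_ci")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

# normalize study input: accept beta/se or hr/ci columns
as_study_estimates <- function(data) {
  data <- tibble::as_tibble(data)
  if (!("beta" %in% names(data)) && "hr" %in% names(data)) {
    data$beta <- log(data$hr)
  }
  if (!("se" %in% names(data)) &&
      all(c("ci_low", "ci_high") %in% names(data))) {
    data$se <- se_from_ci(data$ci_low, data$ci_high)
  }
  if (!all(c("beta", "se") %in% names(data))) {
    stop("need `beta` and `se` columns (or `hr`, `ci_low`, `ci_high`)")
  }
  if (!"cohort" %in% names(data)) {
    data$cohort <- sprintf("study%d", seq_len(nrow(data)))
  }
  data
}

#' Fixed-effects inverse-variance meta-analysis of log hazard ratios
#'
#' Pools per-cohort log HRs with weights `1/se^2`:
#' `pooled_beta = sum(w * beta) / sum(w)`, `pooled_se = 1/sqrt(sum(w))`,
#' two-sided normal p. Cochran's Q and I-squared are reported for
#' inspection but gate nothing. When `bonferroni_alpha` is supplied the
#' result carries a `significant` verdict (`p < bonferroni_alpha`).
#'
#' @param data A data frame with one row per study: `cohort`, and either
#'   `beta` + `se` (log-HR scale) or `hr` + `ci_low` + `ci_high` (converted
#'   through [se_from_ci()]).
#' @param snp_id SNP label.
#' @param cohort_order Cohort order for the direction string (default: row
#'   order).
#' @param bonferroni_alpha Significance threshold for the pooled p, e.g.
#'   [bonferroni_threshold()]; `NULL` for no verdict.
#' @return An object of class `meta_result`.
#' @export
#' @examples
#' studies <- tibble::tibble(
#'   cohort = c("discovery", "replication"),
#'   hr = c(0.92, 0.97), ci_low = c(0.88, 0.93), ci_high = c(0.97, 1.00))
#' fixed_effect_meta(studies)
fixed_effect_meta <- function(data, snp_id = NA_character_,
                              cohort_order = NULL,
                              bonferroni_alpha = NULL) {
  est <- as_study_estimates(data)
  if (nrow(est) == 0) {
    abort_survscan("no study estimates to pool", "survscan_empty_meta")
  }
  if (any(is.na(est$beta)) || any(is.na(est$se)) || any(est$se <= 0)) {
    abort_survscan("every study needs a finite beta and a positive se",
                   "survscan_bad_se")
  }
  w <- 1 / est$se^2
  pooled_beta <- sum(w * est$beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_beta / pooled_se
  p <- 2 * pnorm(-abs(z))
  q <- sum(w * (est$beta - pooled_beta)^2)
  df <- nrow(est) - 1
  i2 <- if (df > 0 && q > df) (q - df) / q else 0
  if (is.null(cohort_order)) cohort_order <- est$cohort
  structure(
    list(
      snp_id = snp_id,
      studies = est,
      pooled_beta = pooled_beta,
      pooled_se = pooled_se,
      pooled_hr = exp(pooled_beta),
      ci_low = exp(pooled_beta - z975 * pooled_se),
      ci_high = exp(pooled_beta + z975 * pooled_se),
      z = z,
      p = p,
      n_studies = nrow(est),
      q_stat = q,
      q_df = df,
      q_p = if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_,
      i2 = i2,
      direction = direction_string(est, cohort_order),
      bonferroni_alpha = bonferroni_alpha,
      significant = if (is.null(bonferroni_alpha)) NA else p < bonferroni_alpha
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat("<meta_result>", if (!is.na(x$snp_id)) x$snp_id, "\n")
  cat(sprintf("  pooled HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d studies\n",
              x$pooled_hr, x$ci_low, x$ci_high, x$p, x$n_studies))
  cat("  direction:", x$direction, "\n")
  if (!is.null(x$bonferroni_alpha)) {
    cat(sprintf("  %s at Bonferroni alpha %.3g\n",
                if (isTRUE(x$significant)) "significant" else
                  "not significant", x$bonferroni_alpha))
  }
  invisible(x)
}

#' Per-study effect direction string
#'
#' One character per cohort in a fixed order: `"+"` for HR above 1, `"-"`
#' for HR below 1, `"0"` for HR exactly 1, and `"?"` for a cohort with no
#' usable estimate (excluded from consistency counts).
#'
#' @param data Study estimates (as for [fixed_effect_meta()]).
#' @param cohort_order Character vector fixing the cohort order.
#' @return A single string of direction characters.
#' @export
#' @examples
#' direction_string(
#'   tibble::tibble(cohort = c("a", "b"), hr = c(0.9, 1.2)), c("a", "b"))
direction_string <- function(data, cohort_order = NULL) {
  est <- as_study_estimates(data)
  if (is.null(cohort_order)) cohort_order <- est$cohort
  beta <- est$beta[match(cohort_order, est$cohort)]
  chars <- dplyr::case_when(
    is.na(beta) ~ "?",
    beta > 0 ~ "+",
    beta < 0 ~ "-",
    TRUE ~ "0"
  )
  paste(chars, collapse = "")
}

#' Count direction characters in a study-effect-direction field
#'
#' Parses a printed direction string (as in replication tables, e.g.
#' `"----- + ---"`; whitespace and both ASCII `-` and Unicode minus are
#' accepted) into per-direction counts.
#'
#' @param direction A direction string.
#' @return A one-row tibble: `n_studies`, `n_protective` (HR < 1), `n_risk`
#'   (HR > 1), `n_null`, `n_missing`.
#' @export
#' @examples
#' direction_counts("----- + ---")
direction_counts <- function(direction) {
  chars <- strsplit(gsub("\\s+", "", direction), "")[[1]]
  chars[chars == "−"] <- "-" # Unicode minus as printed in journals
  bad <- setdiff(chars, c("+", "-", "0", "?"))
  if (length(bad)) {
    stop("unrecognized direction character(s): ",
         paste(unique(bad), collapse = " "))
  }
  tibble::tibble(
    n_studies = length(chars),
    n_protective = sum(chars == "-"),
    n_risk = sum(chars == "+"),
    n_null = sum(chars == "0"),
    n_missing = sum(chars == "?")
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param k Number of SNPs taken into the replication phase.
#' @return `alpha / k`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3)
bonferroni_threshold <- function(alpha = 0.05, k) {
  if (!is_count(k) || k < 1) {
    abort_survscan("`k` must be a positive count", "survscan_bad_k")
  }
  stopifnot(alpha > 0, alpha < 1)
  alpha / k
}

#' Leave-one-cohort-out meta-analysis
#'
#' @param data Study estimates (as for [fixed_effect_meta()]).
#' @param exclude Cohort name to leave out.
#' @param ... Passed to [fixed_effect_meta()].
#' @return A `meta_result` pooling the remaining studies.
#' @export
leave_one_out <- function(data, exclude, ...) {
  est <- as_study_estimates(data)
  if (!exclude %in% est$cohort) {
    stop("cohort '", exclude, "' not present")
  }
  fixed_effect_meta(est[est$cohort != exclude, ], ...)
}

#' Tidy a meta-analysis result
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return Per-study rows plus a final `"pooled"` row — ready for a forest
#'   plot.
#' @export
tidy.meta_result <- function(x, ...) {
  st <- x$studies
  dplyr::bind_rows(
    tibble::tibble(
      term = st$cohort, beta = st$beta, se = st$se,
      hr = exp(st$beta),
      ci_low = exp(st$beta - z975 * st$se),
      ci_high = exp(st$beta + z975 * st$se),
      pooled = FALSE
    ),
    tibble::tibble(
      term = "pooled", beta = x$pooled_beta, se = x$pooled_se,
      hr = x$pooled_hr, ci_low = x$ci_low, ci_high = x$ci_high,
      pooled = TRUE
    )
  )
}

#' One-row summary of a meta-analysis result
#' @param x A `meta_result`.
#' @param ... Unused.
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    snp_id = x$snp_id,
    pooled_beta = x$pooled_beta, pooled_se = x$pooled_se,
    pooled_hr = x$pooled_hr, ci_low = x$ci_low, ci_high = x$ci_high,
    p = x$p, n_studies = x$n_studies,
    direction = x$direction,
    q_stat = x$q_stat, q_p = x$q_p, i2 = x$i2,
    significant = x$significant
  )
}
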