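#' Backward stepwise selection of independently associated SNPs
#'
#' Within a (suggestive) region, reduces the QC-passing SNPs to the subset
#' that stays nominally significant in a joint Cox model with age and sex:
#'
#' 1. *Collinearity guard*: among SNP pairs whose dosage correlation squared
#'    exceeds `r2_prune`, the member with the larger single-SNP p is pruned
#'    (recorded separately from stepwise drops) — near-duplicate dosage
#'    columns make the joint partial likelihood ridge-flat.
#' 2. Fit the joint Cox model with all remaining SNPs + age + sex.
#' 3. Repeatedly remove the SNP with the largest Wald p if that p is at
#'    least `alpha`, refitting after each removal; age and sex are never
#'    removal candidates.
#' 4. Stop when every SNP term has p < `alpha`, or no SNP remains.
#'
#' If the joint model fails to converge, the pruning threshold is tightened
#' stepwise (`r2_prune` -> 0.8 -> 0.5, with a message); if it still fails,
#' an error is raised.
#'
#' @param g A [genotype_matrix()].
#' @param phen A phenotype tibble.
#' @param snp_ids Initial SNP set (default: all SNPs in `g`).
#' @param alpha Nominal significance level for staying in the model
#'   (default 0.05).
#' @param r2_prune Dosage r-squared above which one of a SNP pair is pruned
#'   (default 0.95).
#' @param min_age Baseline age eligibility (default 55).
#' @param roi_id,cohort Labels carried into the result.
#' @return An object of class `selection_result`: fields `initial`,
#'   `pruned`, `dropped` (ordered, with the p at removal), `selected`,
#'   `joint_model` (per-SNP estimates in the final fit), and `marginal`
#'   (the single-SNP scan, used downstream for replication).
#' @export
backward_select <- function(g, phen, snp_ids = NULL, alpha = 0.05,
                            r2_prune = 0.95, min_age = 55,
                            roi_id = "roi", cohort = "cohort") {
  al <- align_cohort(g, phen)
  g <- al$g
  phen <- al$phen
  keep <- !is.na(phen$age) & phen$age >= min_age
  phen <- phen[keep, ]
  d_all <- g$dosage[keep, , drop = FALSE]
  if (is.null(snp_ids)) snp_ids <- colnames(d_all)
  stopifnot(length(snp_ids) >= 1)
  marginal <- suppressMessages(
    scan_snps(g, phen, snp_ids, cohort = cohort, min_age = min_age)
  )
  usable <- marginal$snp_id[marginal$status == "ok"]
  d <- d_all[, usable, drop = FALSE]

  thresholds <- unique(c(r2_prune, pmin(r2_prune, c(0.8, 0.5))))
  fit <- NULL
  pruned <- tibble::tibble(snp_id = character(), kept = character(),
                           r2 = double())
  for (thr in thresholds) {
    pr <- prune_collinear(d, marginal, thr)
    remaining <- pr$remaining
    fit <- joint_cox(d[, remaining, drop = FALSE], phen)
    if (!is.null(fit)) {
      pruned <- pr$pruned
      if (thr != thresholds[1]) {
        message("joint model required tightening the collinearity prune to ",
                "r2 > ", thr)
      }
      break
    }
  }
  if (is.null(fit)) {
    abort_survscan("joint Cox model failed to converge even after pruning",
                   "survscan_joint_nonconvergence")
  }

  dropped <- tibble::tibble(snp_id = character(), p_at_removal = double(),
                            step = integer())
  step <- 0L
  repeat {
    if (length(fit$snp_id) == 0) break
    worst <- which.max(fit$p)
    if (fit$p[worst] < alpha) break
    step <- step + 1L
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      snp_id = fit$snp_id[worst], p_at_removal = fit$p[worst], step = step
    ))
    remaining <- setdiff(fit$snp_id, fit$snp_id[worst])
    if (length(remaining) == 0) {
      fit <- list(snp_id = character(), beta = double(), se = double(),
                  p = double())
      break
    }
    fit <- joint_cox(d[, remaining, drop = FALSE], phen)
    if (is.null(fit)) {
      abort_survscan("joint Cox model lost convergence during backward steps",
                     "survscan_joint_nonconvergence")
    }
  }

  joint <- tibble::tibble(
    snp_id = fit$snp_id, beta = fit$beta, se = fit$se,
    stat = (fit$beta / fit$se)^2,
    p = fit$p
  )
  structure(
    list(
      roi_id = roi_id, cohort = cohort,
      initial = snp_ids,
      unusable = setdiff(snp_ids, usable),
      pruned = pruned,
      dropped = dropped,
      selected = fit$snp_id,
      joint_model = joint,
      marginal = marginal,
      alpha = alpha
    ),
    class = "selection_result"
  )
}

# greedy collinearity pruning; keeps the member with the smaller marginal p
prune_collinear <- function(d, marginal, thr) {
  remaining <- colnames(d)
  pruned <- tibble::tibble(snp_id = character(), kept = character(),
                           r2 = double())
  mp <- setNames(marginal$p, marginal$snp_id)
  repeat {
    if (length(remaining) < 2) break
    cm <- suppressWarnings(
      cor(d[, remaining, drop = FALSE], use = "pairwise.complete.obs")
    )^2
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[top[1], top[2]] <= thr) break
    pair <- remaining[top]
    drop <- pair[which.max(mp[pair])]
    keep <- setdiff(pair, drop)
    pruned <- dplyr::bind_rows(pruned, tibble::tibble(
      snp_id = drop, kept = keep, r2 = cm[top[1], top[2]]
    ))
    remaining <- setdiff(remaining, drop)
  }
  list(remaining = remaining, pruned = pruned)
}

# multi-SNP Cox fit; returns per-SNP estimates or NULL on non-convergence
joint_cox <- function(d, phen) {
  x <- cbind(d, age = phen$age, sex = phen$sex)
  cc <- complete.cases(x) & !is.na(phen$time_years) & !is.na(phen$event)
  x <- x[cc, , drop = FALSE]
  const <- apply(x, 2, function(v) length(unique(v)) < 2)
  snp_cols <- seq_len(ncol(d))
  if (any(const[snp_cols])) return(NULL)
  x <- x[, !const, drop = FALSE]
  y <- survival::Surv(phen$time_years[cc], phen$event[cc])
  ctrl <- survival::coxph.control()
  f <- tryCatch(
    survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL, method = "efron",
                        rownames = NULL, resid = FALSE),
    error = function(e) NULL
  )
  if (is.null(f)) return(NULL)
  beta <- f$coefficients
  v <- diag(f$var)
  if (any(!is.finite(beta)) || any(!is.finite(v)) || any(v <= 0) ||
      any(abs(beta) > 15) || f$iter >= ctrl$iter.max) {
    return(NULL)
  }
  idx <- seq_len(ncol(d)) # SNP columns come first and none were constant
  se <- sqrt(v[idx])
  list(
    snp_id = colnames(d),
    beta = unname(beta[idx]),
    se = unname(se),
    p = pchisq((unname(beta[idx]) / se)^2, 1, lower.tail = FALSE)
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> region '", x$roi_id, "': ",
      length(x$initial), " SNPs in, ", length(x$selected),
      " selected\n", sep = "")
  if (length(x$selected)) cat("  selected:",
                              paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a stepwise selection result
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The final joint-model estimates, one row per selected SNP.
#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$joint_model, roi_id = x$roi_id, .before = 1)
}

#' One-row summary of a stepwise selection
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    roi_id = x$roi_id,
    n_initial = length(x$initial),
    n_pruned = nrow(x$pruned),
    n_dropped = nrow(x$dropped),
    n_selected = length(x$selected)
  )
}

#' Table of replication candidates from stepwise selections
#'
#' One row per selected SNP with its *single-SNP* (marginal) estimate — the
#' quantity carried into replication and meta-analysis — plus its region
#' provenance. A SNP selected in several (merged) regions appears once.
#'
#' @param selections A `selection_result` or list of them.
#' @return An association-style tibble with a `roi_id` column.
#' @export
report_selected <- function(selections) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  rows <- purrr::map_dfr(selections, function(s) {
    if (length(s$selected) == 0) return(tibble::tibble())
    out <- s$marginal[match(s$selected, s$marginal$snp_id), ]
    dplyr::mutate(out, roi_id = s$roi_id, .before = 1)
  })
  if (nrow(rows) == 0) return(rows)
  dplyr::distinct(rows, .data$snp_id, .keep_all = TRUE)
}
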