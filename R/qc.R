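#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against the proportions expected under Hardy-Weinberg equilibrium
#' at the sample allele frequency. Monomorphic samples fit HWE perfectly by
#' construction (statistic 0, p = 1). Vectorized over count triples.
#'
#' @param n_ref Count of reference-homozygotes (dosage 0).
#' @param n_het Count of heterozygotes (dosage 1).
#' @param n_alt Count of coded-allele homozygotes (dosage 2).
#' @return A tibble with the counts, `chisq` and `p`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: chisq 0, p 1
#' hwe_test(30, 30, 40)   # marked heterozygote deficit: p < 1e-4
hwe_test <- function(n_ref, n_het, n_alt) {
  stopifnot(all(n_ref >= 0), all(n_het >= 0), all(n_alt >= 0))
  n <- n_ref + n_het + n_alt
  if (any(n == 0)) {
    abort_survscan("all genotype counts are zero", "survscan_empty_counts")
  }
  p <- (2 * n_alt + n_het) / (2 * n)
  e_ref <- n * (1 - p)^2
  e_het <- n * 2 * p * (1 - p)
  e_alt <- n * p^2
  chisq <- ifelse(
    p == 0 | p == 1, 0,
    (n_ref - e_ref)^2 / e_ref + (n_het - e_het)^2 / e_het +
      (n_alt - e_alt)^2 / e_alt
  )
  tibble::tibble(
    n_ref = n_ref, n_het = n_het, n_alt = n_alt,
    chisq = chisq,
    p = pchisq(chisq, df = 1, lower.tail = FALSE)
  )
}

#' Per-SNP summary statistics for quality control
#'
#' Computes, per SNP: call rate (fraction of non-missing dosages), coded
#' allele frequency (`mean(dosage) / 2`), minor allele frequency, hard-called
#' genotype counts (dosage rounded to the nearest integer), and the HWE
#' chi-square p-value on those hard calls. HWE on fractional dosages is
#' ill-defined, so the test is skipped (`hwe_p = NA`) for SNPs whose
#' imputation R-squared is below `hwe_min_r2` — the HWE filter belongs to
#' genotyped or well-imputed SNPs.
#'
#' @param g A [genotype_matrix()].
#' @param hwe_min_r2 Skip the HWE test when `imp_r2` is known and below this
#'   (default 0.3).
#' @return A tibble, one row per SNP: `snp_id`, `n`, `call_rate`,
#'   `coded_freq`, `maf`, `n_ref`, `n_het`, `n_alt`, `hwe_chisq`, `hwe_p`,
#'   `imp_r2`.
#' @export
snp_summary <- function(g, hwe_min_r2 = 0.3) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  n_total <- nrow(d)
  res <- purrr::map_dfr(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    n_obs <- length(obs)
    freq <- if (n_obs > 0) mean(obs) / 2 else NA_real_
    hard <- pmin(pmax(round(obs), 0), 2)
    counts <- c(sum(hard == 0), sum(hard == 1), sum(hard == 2))
    tibble::tibble(
      snp_id = colnames(d)[j],
      n = n_obs,
      call_rate = n_obs / n_total,
      coded_freq = freq,
      maf = if (is.na(freq)) NA_real_ else min(freq, 1 - freq),
      n_ref = counts[1], n_het = counts[2], n_alt = counts[3]
    )
  })
  r2 <- g$snps$imp_r2
  skip <- !is.na(r2) & r2 < hwe_min_r2
  hwe <- hwe_test(res$n_ref, res$n_het, res$n_alt)
  res$hwe_chisq <- ifelse(skip | res$n == 0, NA_real_, hwe$chisq)
  res$hwe_p <- ifelse(skip | res$n == 0, NA_real_, hwe$p)
  res$imp_r2 <- r2
  res
}

#' QC thresholds for SNP selection
#'
#' Defaults follow the standard candidate-gene dosage workflow: HWE p at
#' least 1e-4 and call rate at least 95% (inclusive bounds), imputation
#' R-squared strictly above 0.8 and minor allele frequency strictly above
#' 0.05.
#'
#' @param hwe_p_min Minimum HWE p-value (inclusive).
#' @param call_rate_min Minimum call rate (inclusive).
#' @param imp_r2_min Imputation R-squared bound (exclusive).
#' @param maf_min Minor-allele-frequency bound (exclusive).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-4, call_rate_min = 0.95,
                          imp_r2_min = 0.8, maf_min = 0.05) {
  vals <- c(hwe_p_min, call_rate_min, imp_r2_min, maf_min)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(
    list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
         imp_r2_min = imp_r2_min, maf_min = maf_min),
    class = "qc_thresholds"
  )
}

#' Apply SNP QC filters
#'
#' A SNP passes iff `hwe_p >= hwe_p_min` AND `call_rate >= call_rate_min`
#' AND `imp_r2 > imp_r2_min` AND `maf > maf_min`. A criterion whose metadata
#' is missing (e.g. no imputation R-squared for a directly genotyped SNP, or
#' HWE skipped for a poorly imputed one) cannot be assessed and does not
#' fail the SNP. Tightening any threshold can only remove SNPs, never add
#' one.
#'
#' @param summaries Per-SNP summary tibble from [snp_summary()] (any table
#'   with `snp_id`, `hwe_p`, `call_rate`, `imp_r2`, `maf` works).
#' @param thresholds A [qc_thresholds()].
#' @return The input with logical columns `fail_hwe`, `fail_call_rate`,
#'   `fail_imp_r2`, `fail_maf` (non-exclusive) and `pass`.
#' @seealso [qc_report()] for per-criterion failure counts.
#' @export
apply_qc <- function(summaries, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  out <- dplyr::mutate(
    summaries,
    fail_hwe = !is.na(.data$hwe_p) & .data$hwe_p < thresholds$hwe_p_min,
    fail_call_rate = !is.na(.data$call_rate) &
      .data$call_rate < thresholds$call_rate_min,
    fail_imp_r2 = !is.na(.data$imp_r2) &
      .data$imp_r2 <= thresholds$imp_r2_min,
    fail_maf = !is.na(.data$maf) & .data$maf <= thresholds$maf_min,
    pass = !(.data$fail_hwe | .data$fail_call_rate |
               .data$fail_imp_r2 | .data$fail_maf)
  )
  out
}

#' Per-criterion QC failure counts
#' @param qc Output of [apply_qc()].
#' @return A one-row tibble counting SNPs failing each criterion
#'   (non-exclusive) and passing overall.
#' @export
qc_report <- function(qc) {
  tibble::tibble(
    n_snps = nrow(qc),
    fail_hwe = sum(qc$fail_hwe),
    fail_call_rate = sum(qc$fail_call_rate),
    fail_imp_r2 = sum(qc$fail_imp_r2),
    fail_maf = sum(qc$fail_maf),
    pass = sum(qc$pass)
  )
}

#' Build regions of interest around candidate genes
#'
#' Each gene is expanded by `margin_bp` on both sides (clipped at position
#' 1); expanded windows on the same chromosome that overlap are merged into
#' a single region — adjacent genes are analysed as one region rather than
#' double-counted. SNPs are assigned to every region containing their
#' position.
#'
#' @param genes A data frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param snps A SNP annotation table with `snp_id`, `chrom`, `pos`.
#' @param margin_bp Flanking margin in base pairs (default 100 kb).
#' @return A tibble, one row per region: `roi_id`, `chrom`, `start`, `end`,
#'   list-columns `genes` and `snp_ids`, and `n_snps`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene = c("A", "B"), chrom = "6",
#'                         start = c(1e6, 1.15e6), end = c(1.01e6, 1.16e6))
#' snps <- tibble::tibble(snp_id = "rs1", chrom = "6", pos = 1.05e6)
#' build_rois(genes, snps)  # windows overlap: one merged region
build_rois <- function(genes, snps, margin_bp = 100000) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) {
    abort_survscan("gene with start > end", "survscan_bad_gene")
  }
  genes <- dplyr::mutate(
    genes,
    w_start = pmax(1, .data$start - margin_bp),
    w_end = .data$end + margin_bp
  )
  out <- list()
  for (chr in unique(genes$chrom)) {
    gch <- dplyr::arrange(genes[genes$chrom == chr, ], .data$w_start)
    cur_start <- gch$w_start[1]
    cur_end <- gch$w_end[1]
    cur_genes <- gch$gene[1]
    flush <- function(s, e, gl) {
      tibble::tibble(
        roi_id = paste(gl, collapse = "+"), chrom = chr,
        start = s, end = e, genes = list(gl)
      )
    }
    if (nrow(gch) > 1) {
      for (i in 2:nrow(gch)) {
        if (gch$w_start[i] <= cur_end) { # overlap: merge
          cur_end <- max(cur_end, gch$w_end[i])
          cur_genes <- c(cur_genes, gch$gene[i])
        } else {
          out[[length(out) + 1]] <- flush(cur_start, cur_end, cur_genes)
          cur_start <- gch$w_start[i]
          cur_end <- gch$w_end[i]
          cur_genes <- gch$gene[i]
        }
      }
    }
    out[[length(out) + 1]] <- flush(cur_start, cur_end, cur_genes)
  }
  rois <- dplyr::bind_rows(out)
  rois$snp_ids <- purrr::pmap(
    rois[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      snps$snp_id[snps$chrom == chrom & snps$pos >= start & snps$pos <= end]
    }
  )
  rois$n_snps <- lengths(rois$snp_ids)
  rois
}
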