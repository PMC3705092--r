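#' Construct a genotype dosage matrix
#'
#' The container the whole pipeline works on: a numeric matrix of expected
#' coded-allele dosages in \[0, 2\] (individuals in rows, SNPs in columns,
#' `NA` for missing), carrying a per-SNP annotation table. Effects are always
#' reported per coded allele as fixed by the annotation; the coded allele is
#' never re-inferred from frequency, so orientation cannot flip between
#' cohorts.
#'
#' @param dosage Numeric matrix, individuals x SNPs, values in \[0, 2\] or
#'   `NA`. Row names are individual ids, column names SNP ids (generated if
#'   absent).
#' @param snps A data frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `gene`, `coded_allele`, `noncoded_allele`, `imp_r2` (missing columns are
#'   filled with `NA`). Row order must match the dosage columns.
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2))
#' snp_info(g)
genotype_matrix <- function(dosage, snps = NULL) {
  stopifnot(is.matrix(dosage), is.numeric(dosage))
  rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    abort_survscan("dosages must lie in [0, 2]", "survscan_bad_dosage")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp_%03d", seq_len(ncol(dosage)))
  }
  if (anyDuplicated(rownames(dosage))) {
    abort_survscan("duplicate individual ids", "survscan_bad_iid")
  }
  if (is.null(snps)) snps <- tibble::tibble(snp_id = colnames(dosage))
  snps <- tibble::as_tibble(snps)
  for (col in c("chrom", "gene", "coded_allele", "noncoded_allele")) {
    if (is.null(snps[[col]])) snps[[col]] <- NA_character_
  }
  if (is.null(snps[["pos"]])) snps[["pos"]] <- NA_integer_
  if (is.null(snps[["imp_r2"]])) snps[["imp_r2"]] <- NA_real_
  if (nrow(snps) != ncol(dosage)) {
    stop("`snps` has ", nrow(snps), " rows but the matrix has ",
         ncol(dosage), " SNP columns")
  }
  if (!identical(as.character(snps$snp_id), colnames(dosage))) {
    stop("`snps$snp_id` must match the dosage column names in order")
  }
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " SNPs\n", sep = "")
  print(head(x$snps), ...)
  invisible(x)
}

#' Per-SNP annotation of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return A tibble with one row per SNP.
#' @export
snp_info <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$snps
}

#' Restrict a genotype matrix to a subset of SNPs
#' @param g A [genotype_matrix()].
#' @param snp_ids Character vector of SNP ids to keep (order respected).
#' @return A `genotype_matrix` with only those SNPs.
#' @export
subset_snps <- function(g, snp_ids) {
  stopifnot(inherits(g, "genotype_matrix"))
  missing <- setdiff(snp_ids, colnames(g$dosage))
  if (length(missing)) {
    stop("SNPs not present: ", paste(missing, collapse = ", "))
  }
  idx <- match(snp_ids, colnames(g$dosage))
  genotype_matrix(g$dosage[, idx, drop = FALSE], g$snps[idx, ])
}
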