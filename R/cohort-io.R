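#' Read genotype dosages from a dosage-VCF or TSV matrix
#'
#' Two on-disk dialects are supported. `"vcf"`: VCF 4.2 with a per-genotype
#' `DS` FORMAT field holding the expected coded(ALT)-allele dosage, one
#' biallelic record per SNP (multi-allelic records are rejected, not split),
#' optional `R2` and `GENE` INFO keys. `"tsv"`: a tab-separated matrix with
#' a header row, first column `iid`, one column per SNP, `.` for missing.
#' Dosages outside \[0, 2\] are rejected, naming the offending record —
#' readers never silently coerce.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return A [genotype_matrix()]; for VCF input the SNP annotation is filled
#'   from the record columns.
#' @export
read_dosages <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_dosage_vcf(path) else read_dosage_tsv(path)
}

#' Write genotype dosages
#'
#' Inverse of [read_dosages()]; dosages are written with six decimals, so a
#' write/read round trip reproduces them to 1e-6.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_dosages <- function(g, path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  if (format == "vcf") write_dosage_vcf(g, path) else write_dosage_tsv(g, path)
}

fmt_dosage <- function(x) ifelse(is.na(x), ".", sprintf("%.6f", x))

write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  lines <- c(
    paste(c("iid", colnames(d)), collapse = "\t"),
    vapply(seq_len(nrow(d)), function(i) {
      paste(c(rownames(d)[i], fmt_dosage(d[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(
                           iid = readr::col_character(),
                           .default = readr::col_double()
                         ))
  if (!identical(names(tab)[1], "iid")) {
    abort_survscan(paste0(path, ": first column must be 'iid'"),
                   "survscan_parse_error")
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort_survscan(
      sprintf("%s: malformed value at line %d, column %d",
              path, prob$row[1] + 1L, prob$col[1]),
      "survscan_parse_error"
    )
  }
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$iid
  check_dosage_bounds(d, path)
  genotype_matrix(d)
}

check_dosage_bounds <- function(d, path) {
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_survscan(
      sprintf("%s: dosage %.6g outside [0, 2] for SNP '%s', individual '%s'",
              path, d[bad[1, 1], bad[1, 2]],
              colnames(d)[bad[1, 2]], rownames(d)[bad[1, 1]]),
      "survscan_bad_dosage"
    )
  }
  invisible(TRUE)
}

write_dosage_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  s <- g$snps
  chrom <- ifelse(is.na(s$chrom), "1", s$chrom)
  pos <- ifelse(is.na(s$pos), seq_len(nrow(s)), s$pos)
  ref <- ifelse(is.na(s$noncoded_allele), "G", s$noncoded_allele)
  alt <- ifelse(is.na(s$coded_allele), "A", s$coded_allele)
  info <- paste0(
    ifelse(is.na(s$imp_r2), "", sprintf("R2=%.4f;", s$imp_r2)),
    ifelse(is.na(s$gene), ".", paste0("GENE=", s$gene))
  )
  info[info == ""] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Expected coded (ALT) allele dosage\">"),
    paste0("##INFO=<ID=R2,Number=1,Type=Float,",
           "Description=\"Imputation quality: dosage variance over ",
           "binomial variance\">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene label\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(chrom[j], pos[j], s$snp_id[j], ref[j], alt[j], ".", "PASS",
            info[j], "DS", fmt_dosage(d[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_dosage_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort_survscan(
      paste0(path, ": multi-allelic record '", fix$ID[which(multi)[1]],
             "' is not supported"),
      "survscan_multiallelic"
    )
  }
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  d <- t(ds)
  colnames(d) <- fix$ID
  r2 <- suppressWarnings(vcfR::extract.info(vcf, "R2", as.numeric = TRUE))
  gene <- vcfR::extract.info(vcf, "GENE")
  snps <- tibble::tibble(
    snp_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    gene = if (is.null(gene)) NA_character_ else gene,
    coded_allele = fix$ALT,
    noncoded_allele = fix$REF,
    imp_r2 = if (is.null(r2)) NA_real_ else r2
  )
  check_dosage_bounds(d, path)
  genotype_matrix(d, snps)
}

#' Read a phenotype table
#'
#' Expects a tab-separated file with header `iid, time_years, event, age,
#' sex` (`sex` coded 0 = male, 1 = female; `.` for missing). Individuals
#' missing any of the five fields are dropped with a warning that counts
#' them; negative follow-up times and non-binary event codes are hard
#' errors, not coerced.
#'
#' @param path File path.
#' @return A phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, na = c(".", "NA", ""), show_col_types = FALSE,
                         col_types = readr::cols(
                           iid = readr::col_character(),
                           time_years = readr::col_double(),
                           event = readr::col_double(),
                           age = readr::col_double(),
                           sex = readr::col_double()
                         ))
  need <- c("iid", "time_years", "event", "age", "sex")
  if (!all(need %in% names(tab))) {
    abort_survscan(
      paste0(path, ": missing column(s) ",
             paste(setdiff(need, names(tab)), collapse = ", ")),
      "survscan_parse_error"
    )
  }
  tab <- tab[, need]
  keep <- complete.cases(tab)
  if (any(!keep)) {
    warning(sum(!keep), " individual(s) dropped for missing phenotype fields")
    tab <- tab[keep, ]
  }
  if (any(tab$time_years < 0)) {
    abort_survscan(paste0(path, ": negative follow-up time"),
                   "survscan_bad_phenotype")
  }
  if (!all(tab$event %in% c(0, 1)) || !all(tab$sex %in% c(0, 1))) {
    abort_survscan(paste0(path, ": event and sex must be coded 0/1"),
                   "survscan_bad_phenotype")
  }
  if (anyDuplicated(tab$iid)) {
    abort_survscan(paste0(path, ": duplicate iid"), "survscan_bad_phenotype")
  }
  tab$event <- as.integer(tab$event)
  tab$sex <- as.integer(tab$sex)
  tibble::as_tibble(tab)
}

#' Write a phenotype table
#' @param phen A phenotype tibble (`iid, time_years, event, age, sex`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_tsv(phen[, c("iid", "time_years", "event", "age", "sex")],
                   path)
  invisible(path)
}

#' Read/write a SNP annotation table
#'
#' Tab-separated, header `snp_id, chrom, pos, gene, coded_allele,
#' noncoded_allele, imp_r2`, `.` for missing. The coded allele recorded here
#' fixes the orientation of every downstream effect estimate.
#'
#' @param path File path.
#' @return A tibble with one row per SNP.
#' @export
read_snp_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_tsv(path, na = c(".", "NA", ""), show_col_types = FALSE,
                  col_types = readr::cols(
                    snp_id = readr::col_character(),
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    gene = readr::col_character(),
                    coded_allele = readr::col_character(),
                    noncoded_allele = readr::col_character(),
                    imp_r2 = readr::col_double()
                  ))
}

#' @rdname read_snp_annotation
#' @param snps A SNP annotation tibble.
#' @export
write_snp_annotation <- function(snps, path) {
  readr::write_tsv(snps, path, na = ".")
  invisible(path)
}

assoc_cols <- c("snp_id", "cohort", "coded_allele", "coded_freq",
                "beta", "se", "hr", "ci_low", "ci_high", "p")

#' Read/write per-SNP association results
#'
#' Tab-separated with columns `snp_id, cohort, coded_allele, coded_freq,
#' beta, se, hr, ci_low, ci_high, p`; numbers are written with enough digits
#' that a round trip is lossless to 10 significant digits. Extra columns
#' (e.g. `n`, `n_events`, `stat`, `status`) are preserved.
#'
#' @param results An association result tibble (see [scan_snps()]).
#' @param path File path.
#' @return `write_assoc_table()` returns `path` invisibly;
#'   `read_assoc_table()` returns the tibble.
#' @export
write_assoc_table <- function(results, path) {
  missing <- setdiff(assoc_cols, names(results))
  for (col in missing) results[[col]] <- NA
  first <- intersect(c(assoc_cols, names(results)), names(results))
  readr::write_tsv(results[, unique(first)], path, na = ".")
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_tsv(path, na = c(".", "NA", ""), show_col_types = FALSE,
                  col_types = readr::cols(
                    snp_id = readr::col_character(),
                    cohort = readr::col_character(),
                    coded_allele = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Align a genotype matrix and phenotype table on individual ids
#'
#' @param g A [genotype_matrix()].
#' @param phen A phenotype tibble.
#' @return A list with `g` and `phen` restricted to the shared individuals,
#'   in genotype row order. Phenotyped individuals absent from the genotype
#'   matrix are an alignment error.
#' @export
align_cohort <- function(g, phen) {
  stopifnot(inherits(g, "genotype_matrix"))
  extra <- setdiff(phen$iid, rownames(g$dosage))
  if (length(extra)) {
    abort_survscan(
      paste0("phenotyped individuals missing from genotypes: ",
             paste(head(extra, 3), collapse = ", "),
             if (length(extra) > 3) ", ..."),
      "survscan_alignment_error"
    )
  }
  ids <- intersect(rownames(g$dosage), phen$iid)
  idx <- match(ids, rownames(g$dosage))
  list(
    g = genotype_matrix(g$dosage[idx, , drop = FALSE], g$snps),
    phen = phen[match(ids, phen$iid), ]
  )
}
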