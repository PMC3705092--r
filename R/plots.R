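#' Forest plot of a meta-analysis result
#'
#' Per-study hazard ratios with 95% CIs on a log scale, the pooled estimate
#' at the bottom, and a reference line at HR = 1.
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_result <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Hazard ratio per coded allele (log scale)", y = NULL,
      title = if (!is.na(object$snp_id)) object$snp_id else NULL,
      subtitle = sprintf("pooled HR %.2f (%.2f-%.2f), p = %.2g",
                         object$pooled_hr, object$ci_low, object$ci_high,
                         object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Null-maximum distribution of a permutation result
#'
#' Histogram of the B region-wide maximum statistics under the permutation
#' null, with the observed maximum marked.
#'
#' @param object A `perm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_result <- function(object, ...) {
  nm <- tibble::tibble(max_stat = object$null_maxima)
  obs <- max(object$observed$stat, na.rm = TRUE)
  ggplot2::ggplot(nm, ggplot2::aes(x = .data$max_stat)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "red") +
    ggplot2::labs(
      x = "Region-wide maximum Wald chi-square (null)", y = "Replicates",
      title = object$roi_id,
      subtitle = sprintf("observed max %.2f, region empirical p = %s",
                         obs, format(object$roi_emp_p))
    ) +
    ggplot2::theme_minimal()
}

#' Regional association plot for a scan
#'
#' SNP position against -log10 of the Wald p-value.
#'
#' @param assoc An association tibble from [scan_snps()].
#' @param snps SNP annotation with `snp_id` and `pos` (only needed when the
#'   assoc table lacks positions).
#' @return A ggplot object.
#' @export
plot_scan <- function(assoc, snps = NULL) {
  if (!"pos" %in% names(assoc)) {
    stopifnot(!is.null(snps))
    assoc <- dplyr::left_join(assoc, snps[, c("snp_id", "pos")],
                              by = "snp_id")
  }
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$pos / 1e6,
                                      y = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}
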