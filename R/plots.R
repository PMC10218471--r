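#' Manhattan plot of an association scan
#'
#' @param scan An `assoc_scan` data frame.
#' @param lines Thresholds from [significance_lines()].
#' @return A ggplot object (requires \pkg{ggplot2}).
#' @export
plot_manhattan <- function(scan, lines = significance_lines()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  chroms <- unique(scan$chrom)
  offs <- stats::setNames(
    cumsum(c(0, utils::head(tapply(scan$pos, scan$chrom, max)[chroms], -1))),
    chroms)
  df <- data.frame(x = scan$pos + offs[scan$chrom],
                   logp = -log10(pmax(scan$p, 1e-300)),
                   chrom = scan$chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$logp,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(lines$genomewide),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(lines$suggestive),
                        colour = "blue") +
    ggplot2::labs(x = "genomic position", y = "-log10(p)")
}

#' QQ plot of scan p-values
#'
#' @param p Vector of p-values.
#' @return A ggplot object annotated with the genomic inflation factor.
#' @export
plot_qq <- function(p) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- sort(p[!is.na(p)])
  df <- data.frame(expected = -log10(stats::ppoints(length(p))),
                   observed = -log10(pmax(p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)",
                  subtitle = sprintf("lambda_GC = %.3f",
                                     genomic_inflation(p)))
}
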