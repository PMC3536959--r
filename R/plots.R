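#' Quantile-quantile plot of association p-values
#'
#' Observed versus expected `-log10(p)` under the uniform null, with the
#' identity line and the median-based genomic-control inflation factor in
#' the subtitle.
#'
#' @param results Data frame with a p-value column.
#' @param p_col Name of the p-value column (default `"p"`).
#' @return A ggplot object.
#' @export
plot_qq <- function(results, p_col = "p") {
  p <- results[[p_col]]
  p <- sort(p[!is.na(p)])
  n <- length(p)
  stopifnot(n > 0)
  df <- tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(pmax(p, 1e-300))
  )
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p))),
      subtitle = paste0("lambda_GC = ", signif(lambda, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of association results
#'
#' `-log10(p)` against cumulative genomic position, chromosomes in
#' alternating shades, with an optional significance threshold line.
#'
#' @param results Data frame with `chrom`, `pos` and a p-value column.
#' @param p_col Name of the p-value column (default `"p"`).
#' @param threshold Optional significance threshold to draw.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, p_col = "p", threshold = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(results)))
  df <- tibble(
    chrom = as.character(results$chrom),
    pos = results$pos,
    logp = -log10(pmax(results[[p_col]], 1e-300))
  )
  df <- df[!is.na(df$logp), ]
  chrom_levels <- unique(df$chrom[order(suppressWarnings(
    as.numeric(df$chrom)), df$chrom)])
  df$chrom <- factor(df$chrom, levels = chrom_levels)
  offsets <- c(0, cumsum(vapply(split(df$pos, df$chrom), function(x) {
    if (length(x) == 0) 0 else max(x)
  }, numeric(1))))
  df$x <- df$pos + offsets[as.integer(df$chrom)]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$logp,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey30", "steelblue"),
                   length.out = length(chrom_levels))) +
    ggplot2::labs(x = "Genomic position",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  g
}

#' @exportS3Method ggplot2::autoplot
autoplot.site_assoc <- function(object, ...) {
  plot_qq(object, p_col = "p")
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_assoc <- function(object, ...) {
  if (all(c("chrom", "pos") %in% names(object))) {
    plot_manhattan(object)
  } else {
    plot_qq(object)
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.gc_result <- function(object, ...) {
  plot_qq(object$results, p_col = "p_gc")
}
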