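#' Bar plot of the methylation frequency spectrum
#'
#' @param spectrum A `cream_spectrum` object (see [frequency_spectrum()]).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "cream_spectrum"))
  ggplot2::ggplot(spectrum$spectrum, ggplot2::aes(x = .data$k, y = .data$n_loci)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::scale_x_continuous(breaks = scales_int_breaks) +
    ggplot2::labs(x = "Samples methylated (k)", y = "Methylated loci",
                  title = "Methylation frequency spectrum") +
    ggplot2::theme_minimal()
}

scales_int_breaks <- function(lims) {
  b <- pretty(lims)
  b[b == floor(b)]
}

#' PCA scatter of methylotypes
#'
#' @param object A `cream_pca` object.
#' @param ... Unused.
#' @return A ggplot object; points are coloured by clonal line when the
#'   scores carry a `line` column.
#' @method autoplot cream_pca
#' @export
autoplot.cream_pca <- function(object, ...) {
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$var_explained[i])
  aes <- if ("line" %in% names(object$scores)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$line)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2), title = "Methylotype PCA") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Gene vs methylated-locus density along the genome
#'
#' @param bins A [bin_densities()] table.
#' @return A ggplot object, one panel per chromosome.
#' @export
plot_bin_density <- function(bins) {
  long <- bins |>
    pivot_longer(c("n_genes", "n_methylated"), names_to = "track",
                 values_to = "count") |>
    mutate(track = dplyr::recode(.data$track, n_genes = "genes",
                                 n_methylated = "methylated loci"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_start / 1e6, y = .data$count,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Features per bin", colour = NULL) +
    ggplot2::theme_minimal()
}
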