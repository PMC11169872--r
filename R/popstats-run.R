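#' Run every population-level analysis on a methylotype matrix
#'
#' Computes the frequency spectrum, the subculture rank test, the PCA, the
#' 500-kb density table with its gene-methylation Spearman correlation and,
#' when a gene-to-term map is supplied, the proximity-based term
#' enrichment. Each result is also written as TSV when `dir` is given.
#'
#' @param x A `cream_methylotypes` object.
#' @param metadata Tibble `sample`, `line`, `subculture`.
#' @param genes Gene tibble (`chrom`, `start`, `end`, `gene_id`) or GFF3
#'   path; enables the density and enrichment analyses.
#' @param genome Sequences or named chromosome lengths; required with
#'   `genes`.
#' @param term_map Tibble `gene_id`, `term` or two-column TSV path;
#'   optional.
#' @param dir Output directory; `NULL` keeps results in memory.
#' @param bin_size Density bin width in bp.
#' @param window Transcript proximity window in bp.
#' @param alpha Enrichment significance threshold (BH-adjusted).
#' @return A list with `spectrum`, `subculture`, `pca`, and where inputs
#'   allow, `bins`, `rho`, `proximity`, `enrichment`.
#' @export
run_popstats <- function(x, metadata, genes = NULL, genome = NULL,
                         term_map = NULL, dir = NULL, bin_size = 5e5,
                         window = 1000, alpha = 0.10) {
  stopifnot(inherits(x, "cream_methylotypes"))
  if (is.character(genes)) genes <- read_gff3_genes(genes)
  if (is.character(term_map)) {
    term_map <- readr::read_tsv(term_map, show_col_types = FALSE,
                                col_names = c("gene_id", "term"))
  }
  out <- list(
    spectrum = frequency_spectrum(x, metadata),
    subculture = subculture_test(x, metadata),
    pca = pca_methylotypes(x, metadata)
  )

  if (!is.null(genes)) {
    if (is.null(genome)) abort("`genome` is required with `genes`.")
    meth_loci <- filter(x$loci, .data$locus_call == "methylated")
    out$bins <- bin_densities(meth_loci, genes, genome, bin_size = bin_size)
    if (nrow(out$bins) >= 3) {
      out$rho <- spearman_rho(out$bins$n_genes, out$bins$n_methylated)
    } else {
      inform("Fewer than 3 bins: density correlation skipped (reduce `bin_size`).")
      out$rho <- NA_real_
    }
    out$proximity <- proximity_annotation(x$loci, genes, window = window)
    if (!is.null(term_map)) {
      target <- out$proximity |>
        inner_join(select(x$loci, "locus_id", "locus_call"), by = "locus_id") |>
        filter(.data$locus_call == "methylated") |>
        pull(.data$gene_id)
      background <- out$proximity$gene_id
      out$enrichment <- term_enrichment(unique(target), unique(background),
                                        term_map, alpha = alpha)
    } else {
      inform("No term map supplied; enrichment stage skipped.")
    }
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$spectrum$spectrum, file.path(dir, "spectrum.tsv"))
    readr::write_tsv(out$subculture, file.path(dir, "subculture_test.tsv"))
    readr::write_tsv(tidy(out$pca), file.path(dir, "pca_coordinates.tsv"))
    readr::write_tsv(glance(out$pca), file.path(dir, "pca_variance.tsv"))
    if (!is.null(out$bins)) {
      readr::write_tsv(out$bins, file.path(dir, "bin_densities.tsv"))
      readr::write_tsv(tibble(spearman_rho = out$rho), file.path(dir, "density_rho.tsv"))
    }
    if (!is.null(out$enrichment)) {
      readr::write_tsv(out$enrichment, file.path(dir, "enrichment.tsv"))
    }
  }
  out
}
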