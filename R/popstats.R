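binary_view <- function(x) {
  if (inherits(x, "cream_methylotypes")) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  abort("Expected a `cream_methylotypes` object or a binary samples-by-loci matrix.")
}

#' Methylation frequency spectrum
#'
#' Counts methylated loci by the number of samples carrying a methylated
#' status. In a clonal population the spectrum shows characteristic peaks:
#' monomorphic loci (methylated in every sample), line-exclusive loci
#' (methylated in exactly the samples of one clonal line) and singletons
#' (one sample only).
#'
#' @param x A `cream_methylotypes` object or binary samples-by-loci matrix.
#' @param metadata Optional tibble `sample`, `line`; enables line-exclusive
#'   counts. All matrix samples must be present.
#' @return A list of class `cream_spectrum`: `spectrum` (tibble `k`,
#'   `n_loci`, for k >= 1), `n_samples`, `n_methylated_loci`, `monomorphic`,
#'   `singletons`, and `line_exclusive` (tibble `line`, `n_loci`) when
#'   metadata is given.
#' @export
frequency_spectrum <- function(x, metadata = NULL) {
  bin <- binary_view(x)
  n_samples <- nrow(bin)
  k <- colSums(bin == 1, na.rm = TRUE)
  meth <- k >= 1
  tab <- table(k[meth])
  spectrum <- tibble(k = as.integer(names(tab)), n_loci = as.integer(tab))
  out <- list(
    spectrum = spectrum, n_samples = n_samples,
    n_methylated_loci = sum(meth),
    monomorphic = sum(k == n_samples),
    singletons = sum(k == 1)
  )
  if (!is.null(metadata)) {
    if (!all(rownames(bin) %in% metadata$sample)) {
      abort("Every sample in the matrix must appear in `metadata`.")
    }
    lines <- unique(metadata$line)
    out$line_exclusive <- bind_rows(lapply(lines, function(ln) {
      in_line <- rownames(bin) %in% metadata$sample[metadata$line == ln]
      all_in <- colSums(bin[in_line, , drop = FALSE] == 1, na.rm = TRUE) == sum(in_line) &
        !apply(is.na(bin[in_line, , drop = FALSE]), 2, any)
      none_out <- colSums(bin[!in_line, , drop = FALSE] == 1, na.rm = TRUE) == 0
      tibble(line = ln, n_samples = sum(in_line), n_loci = sum(all_in & none_out))
    }))
  }
  structure(out, class = "cream_spectrum")
}

#' @export
print.cream_spectrum <- function(x, ...) {
  cat(sprintf("Methylation frequency spectrum over %d samples\n", x$n_samples))
  cat(sprintf("  methylated loci: %d (monomorphic %d, singletons %d)\n",
              x$n_methylated_loci, x$monomorphic, x$singletons))
  if (!is.null(x$line_exclusive)) {
    for (i in seq_len(nrow(x$line_exclusive))) {
      cat(sprintf("  exclusive to %s (%d samples): %d\n",
                  x$line_exclusive$line[i], x$line_exclusive$n_samples[i],
                  x$line_exclusive$n_loci[i]))
    }
  }
  invisible(x)
}

#' @describeIn frequency_spectrum Spectrum as a tidy tibble.
#' @param ... Unused.
#' @method tidy cream_spectrum
#' @export
tidy.cream_spectrum <- function(x, ...) x$spectrum

#' Kruskal-Wallis rank test
#'
#' One-way ANOVA on ranks with midrank tie correction; the H statistic is
#' referred to a chi-square distribution with `groups - 1` degrees of
#' freedom. Used to test whether per-sample methylated-locus counts change
#' with the number of subcultures.
#'
#' @param values Numeric response (e.g. methylated-locus counts).
#' @param groups Grouping vector (e.g. subculture number).
#' @return Tibble `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  if (length(values) != length(groups)) abort("`values` and `groups` lengths differ.")
  if (stats::var(rank(values)) == 0) {
    # all observations tied: H = 0 by convention, avoids 0/0 in the tie term
    return(tibble(statistic = 0, df = nlevels(groups) - 1L, p.value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}

#' Test methylated-locus counts against subculture number
#'
#' @param x A `cream_methylotypes` object or binary matrix.
#' @param metadata Tibble `sample`, `subculture`.
#' @return Tibble with the per-sample counts test: `statistic`, `df`,
#'   `p.value`, plus `n_samples` and `n_groups`.
#' @export
subculture_test <- function(x, metadata) {
  bin <- binary_view(x)
  if (!all(rownames(bin) %in% metadata$sample)) {
    abort("Every sample in the matrix must appear in `metadata`.")
  }
  counts <- rowSums(bin == 1, na.rm = TRUE)
  sub <- metadata$subculture[match(rownames(bin), metadata$sample)]
  res <- kruskal_wallis_test(counts, sub)
  mutate(res, n_samples = length(counts), n_groups = dplyr::n_distinct(sub))
}

#' Principal component analysis of methylotypes
#'
#' PCA of the binary methylated view: masked cells (ambiguous/missing) are
#' imputed with the locus mean, columns are centered but not scaled, and
#' the decomposition is computed by SVD. Variance-explained fractions are
#' non-negative and sum to 1 over all components.
#'
#' @param x A `cream_methylotypes` object or binary matrix.
#' @param metadata Optional tibble `sample`, `line` carried onto the scores.
#' @return Object of class `cream_pca`: `scores` (tibble of sample
#'   coordinates), `var_explained`, `sdev`, `n_loci`, `zero_variance`.
#' @export
pca_methylotypes <- function(x, metadata = NULL) {
  bin <- binary_view(x)
  if (nrow(bin) < 2 || ncol(bin) < 2) abort("PCA needs >= 2 samples and >= 2 loci.")
  mu <- colMeans(bin, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(bin))) bin[is.na(bin[, j]), j] <- mu[j]
  pc <- prcomp(bin, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  zero <- tot == 0
  var_explained <- if (zero) rep(0, length(pc$sdev)) else pc$sdev^2 / tot
  scores <- as_tibble(pc$x, .name_repair = "minimal")
  scores <- bind_cols(tibble(sample = rownames(bin)), scores)
  if (!is.null(metadata)) {
    scores <- left_join(scores, metadata[c("sample", "line")], by = "sample")
  }
  structure(
    list(scores = scores, var_explained = var_explained, sdev = pc$sdev,
         n_loci = ncol(bin), zero_variance = zero),
    class = "cream_pca"
  )
}

#' @export
print.cream_pca <- function(x, ...) {
  cat(sprintf("Methylotype PCA: %d samples, %d loci\n", nrow(x$scores), x$n_loci))
  ve <- utils::head(x$var_explained, 3)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "), "\n")
  if (x$zero_variance) cat("  note: zero-variance input, all components flat\n")
  invisible(x)
}

#' @describeIn pca_methylotypes Sample coordinates as a tibble.
#' @param ... Unused.
#' @method tidy cream_pca
#' @export
tidy.cream_pca <- function(x, ...) x$scores

#' @describeIn pca_methylotypes Variance-explained per component.
#' @method glance cream_pca
#' @export
glance.cream_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         sdev = x$sdev, var_explained = x$var_explained)
}

genome_lengths <- function(genome) {
  if (is(genome, "DNAStringSet") || is.character(genome) && !is.null(names(genome))) {
    g <- as_genome(genome)
    return(setNames(Biostrings::width(g), names(g)))
  }
  if (is.numeric(genome) && !is.null(names(genome))) return(genome)
  abort("`genome` must be sequences or a named vector of chromosome lengths.")
}

#' Gene and methylated-locus density in genomic bins
#'
#' Tiles each chromosome with fixed-width bins (default 500 kb, final
#' partial bin included) and counts features by the bin containing their
#' start coordinate.
#'
#' @param loci Tibble `chrom`, `start` of (methylated) loci.
#' @param genes Tibble `chrom`, `start` of genes.
#' @param genome Sequences or named chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return Tibble `chrom`, `bin_start`, `bin_end`, `n_genes`,
#'   `n_methylated`.
#' @export
bin_densities <- function(loci, genes, genome, bin_size = 5e5) {
  lens <- genome_lengths(genome)
  check_feats <- function(x, what) {
    if (nrow(x) == 0) return(invisible())
    bad <- !(x$chrom %in% names(lens)) | x$start >= lens[x$chrom] | x$start < 0
    if (any(bad)) abort(paste0(sum(bad), " ", what, " feature(s) outside the genome."))
  }
  check_feats(loci, "locus")
  check_feats(genes, "gene")
  bins <- bind_rows(lapply(names(lens), function(cn) {
    starts <- seq(0, lens[[cn]] - 1, by = bin_size)
    tibble(chrom = cn, bin_start = starts,
           bin_end = pmin(starts + bin_size, lens[[cn]]))
  }))
  count_in_bins <- function(x) {
    if (nrow(x) == 0) return(rep(0L, nrow(bins)))
    key <- paste(x$chrom, (x$start %/% bin_size) * bin_size)
    bkey <- paste(bins$chrom, bins$bin_start)
    as.integer(table(factor(key, levels = bkey)))
  }
  bins$n_genes <- count_in_bins(genes)
  bins$n_methylated <- count_in_bins(loci)
  bins
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (tie-aware). Returns `NA` with a warning
#' when either vector is constant, where the rank correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("Constant vector: Spearman correlation undefined.")
    return(NA_real_)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Assign loci to transcripts within a window
#'
#' A locus is assigned to every transcript whose interval, expanded by
#' `window` bp on both sides, overlaps the locus by at least one
#' nucleotide.
#'
#' @param loci Tibble `locus_id`, `chrom`, `start`, `end`.
#' @param transcripts Tibble `chrom`, `start`, `end`, `gene_id`.
#' @param window Expansion in bp (default 1 kb).
#' @return Tibble `locus_id`, `gene_id` of assignments.
#' @export
proximity_annotation <- function(loci, transcripts, window = 1000) {
  if (window < 0) abort("`window` must be >= 0.")
  if (nrow(loci) == 0 || nrow(transcripts) == 0) {
    return(tibble(locus_id = integer(0), gene_id = character(0)))
  }
  lg <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  tg <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(pmax(transcripts$start + 1L - window, 1L),
                     transcripts$end + window)
  )
  hits <- GenomicRanges::findOverlaps(lg, tg, minoverlap = 1L)
  tibble(
    locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
    gene_id = transcripts$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
}

#' Over-representation of terms in a target gene set
#'
#' One-sided hypergeometric test per term against a flat gene-to-term map,
#' with Benjamini-Hochberg adjustment across terms; terms with adjusted
#' p below `alpha` are flagged significant. The target must be a subset of
#' the background universe (e.g. methylated loci near transcripts vs all
#' captured loci near transcripts); duplicate gene ids are collapsed.
#'
#' @param target Character vector of target gene ids.
#' @param background Character vector of background gene ids.
#' @param term_map Tibble `gene_id`, `term`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Tibble per term: `term`, `target_hits`, `background_hits`,
#'   `target_size`, `background_size`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
term_enrichment <- function(target, background, term_map, alpha = 0.10) {
  target <- unique(target)
  background <- unique(background)
  if (!all(target %in% background)) abort("`target` must be a subset of `background`.")
  term_map <- distinct(term_map[c("gene_id", "term")]) |>
    filter(.data$gene_id %in% background)
  N <- length(background)
  n <- length(target)
  res <- term_map |>
    group_by(.data$term) |>
    summarise(
      background_hits = dplyr::n_distinct(.data$gene_id),
      target_hits = sum(unique(.data$gene_id) %in% target),
      .groups = "drop"
    ) |>
    mutate(
      target_size = n, background_size = N,
      p_value = phyper(.data$target_hits - 1L, .data$background_hits,
                       N - .data$background_hits, n, lower.tail = FALSE)
    ) |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_adjusted < alpha) |>
    arrange(.data$p_value)
  res
}
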