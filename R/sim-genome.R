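BASE_CODES <- utf8ToInt("ACGT")

random_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

#' Simulate a genome with GC-rich genic blocks
#'
#' Draws i.i.d. bases at `background_gc` outside genic blocks and `genic_gc`
#' inside them. Blocks are placed by drawing candidate start positions
#' uniformly along each chromosome and greedily dropping overlaps, so the
#' number of genes per genomic bin varies like a thinned Poisson process --
#' the gene-density heterogeneity that the density-correlation analysis
#' exercises. Deterministic for a given `seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named `DNAStringSet`) and `genes` (tibble
#'   `chrom`, `start`, `end`, `gene_id`; 0-based half-open).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "cream_sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  L <- config$chrom_length
  blk <- config$genic_block_length
  n_blocks <- max(0L, as.integer(round(L * config$genic_block_fraction / blk)))

  chroms <- character(config$n_chrom)
  genes <- vector("list", config$n_chrom)
  for (ci in seq_len(config$n_chrom)) {
    codes <- random_bases(L, config$background_gc)
    starts <- integer(0)
    if (n_blocks > 0 && L > blk) {
      cand <- sort(sample.int(L - blk, n_blocks, replace = TRUE)) - 1L
      keep <- logical(length(cand))
      prev_end <- -1L
      for (i in seq_along(cand)) {
        if (cand[i] >= prev_end) {
          keep[i] <- TRUE
          prev_end <- cand[i] + blk
        }
      }
      starts <- cand[keep]
      for (s in starts) codes[(s + 1L):(s + blk)] <- random_bases(blk, config$genic_gc)
    }
    chroms[ci] <- intToUtf8(BASE_CODES[codes])
    genes[[ci]] <- tibble(
      chrom = paste0("chr", ci), start = starts, end = starts + blk,
      gene_id = sprintf("gene_%d_%03d", ci, seq_along(starts))
    )
  }
  names(chroms) <- paste0("chr", seq_len(config$n_chrom))
  list(genome = Biostrings::DNAStringSet(chroms), genes = bind_rows(genes))
}

#' Simulate layered clonal-population methylomes
#'
#' Every CCGG site in the genome is assigned independently: methylated in the
#' shared base layer with probability `base_methylation_prob`; then flipped
#' for a whole clonal line with probability `line_epimutation_rate` (one draw
#' per line, shared by all its samples); then flipped per sample with
#' probability `sample_epimutation_rate` (singleton epimutations). The
#' resulting per-sample states produce the characteristic frequency-spectrum
#' peaks at all samples, one line, and single samples.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param config A [sim_config()].
#' @return A list with:
#'   * `samples`: tibble `sample`, `line`, `subculture`;
#'   * `methylomes`: tibble `sample`, `chrom`, `pos` of methylated CCGG
#'     motif starts (0-based);
#'   * `sites`: tibble `chrom`, `pos`, `base_methylated`, plus one logical
#'     state column per sample.
#' @export
simulate_methylomes <- function(genome, config) {
  stopifnot(inherits(config, "cream_sim_config"))
  genome <- as_genome(genome)
  set.seed(derive_seed(config$seed, "methylome"))

  sites <- find_sites_set(genome, "CCGG")
  ns <- nrow(sites)
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  samples <- tibble(
    sample = sprintf("S%02d", seq_len(config$n_lines * config$n_samples)),
    line = rep(lines, each = config$n_samples),
    subculture = sample(seq(config$subculture_range[1], config$subculture_range[2]),
                        config$n_lines * config$n_samples, replace = TRUE)
  )

  base_state <- runif(ns) < config$base_methylation_prob
  line_flip <- matrix(runif(ns * config$n_lines) < config$line_epimutation_rate,
                      nrow = ns, dimnames = list(NULL, lines))
  state <- matrix(FALSE, nrow = ns, ncol = nrow(samples),
                  dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    flip_s <- runif(ns) < config$sample_epimutation_rate
    state[, j] <- xor(xor(base_state, line_flip[, samples$line[j]]), flip_s)
  }

  meth_rows <- lapply(samples$sample, function(s) {
    idx <- which(state[, s])
    tibble(sample = s, chrom = sites$chrom[idx], pos = sites$pos[idx])
  })
  site_tbl <- bind_cols(sites, tibble(base_methylated = base_state), as_tibble(state))
  list(samples = samples, methylomes = bind_rows(meth_rows), sites = site_tbl)
}
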