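#' Configuration of a synthetic CREAM experiment
#'
#' Bundles the generator parameters for a clonal-population CREAM experiment:
#' a multi-chromosome genome with GC-rich genic blocks, per-sample CpG
#' methylomes layered as a shared base, clonal-line-specific flips and
#' per-sample singleton epimutations, dual MspI/HpaII digestion with 200-400
#' bp size selection and paired-end 150 bp sequencing.
#'
#' Defaults describe the study conditions the package is validated under:
#' two sister clonal lines of ten samples each on a 10 Mb (2 x 5 Mb) genome
#' with cannabis-like 33% background GC, 30 insert copies per selected
#' fragment and error-free reads.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 1 kb).
#' @param background_gc GC fraction of intergenic sequence.
#' @param genic_block_fraction Fraction of each chromosome covered by
#'   gene-dense, GC-rich blocks.
#' @param genic_gc GC fraction inside genic blocks.
#' @param genic_block_length Length of one genic block in bp.
#' @param n_lines Number of clonal lines.
#' @param n_samples Samples per line.
#' @param base_methylation_prob Probability a CCGG site is methylated in the
#'   shared base layer.
#' @param line_epimutation_rate Per-site probability of a line-wide state
#'   flip (same flip for every sample of the line).
#' @param sample_epimutation_rate Per-site probability of an independent
#'   per-sample state flip (singleton epimutations).
#' @param depth Mean sequenced copies per selected fragment (Poisson).
#' @param read_length Read length in bp.
#' @param substitution_error_rate Per-base substitution error probability.
#' @param size_min,size_max Inclusive size-selection window in bp.
#' @param subculture_range Integer range of subculture counts assigned
#'   uniformly to samples.
#' @param seed Mandatory integer seed; every stochastic stage derives its
#'   stream from it.
#' @return A list of class `cream_sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 5e6,
                       background_gc = 0.33, genic_block_fraction = 0.30,
                       genic_gc = 0.50, genic_block_length = 30000,
                       n_lines = 2, n_samples = 10,
                       base_methylation_prob = 0.40,
                       line_epimutation_rate = 0.05,
                       sample_epimutation_rate = 0.01,
                       depth = 30, read_length = 150,
                       substitution_error_rate = 0,
                       size_min = 200, size_max = 400,
                       subculture_range = c(6L, 11L),
                       seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  cfg <- list(
    n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
    background_gc = background_gc, genic_block_fraction = genic_block_fraction,
    genic_gc = genic_gc, genic_block_length = as.integer(genic_block_length),
    n_lines = as.integer(n_lines), n_samples = as.integer(n_samples),
    base_methylation_prob = base_methylation_prob,
    line_epimutation_rate = line_epimutation_rate,
    sample_epimutation_rate = sample_epimutation_rate,
    depth = depth, read_length = as.integer(read_length),
    substitution_error_rate = substitution_error_rate,
    size_min = as.integer(size_min), size_max = as.integer(size_max),
    subculture_range = as.integer(subculture_range),
    seed = as.integer(seed)
  )
  fracs <- c("background_gc", "genic_block_fraction", "genic_gc",
             "base_methylation_prob", "line_epimutation_rate",
             "sample_epimutation_rate", "substitution_error_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]."))
  }
  if (cfg$n_chrom < 1 || cfg$chrom_length < 1000) {
    abort("Need at least one chromosome of >= 1 kb.")
  }
  if (cfg$n_lines < 1 || cfg$n_samples < 1) abort("Need >= 1 line and >= 1 sample per line.")
  if (cfg$depth < 0) abort("`depth` must be >= 0.")
  if (cfg$size_min > cfg$size_max || cfg$size_min < 0) abort("Invalid size-selection window.")
  structure(cfg, class = "cream_sim_config")
}

# small deterministic seed derivation so each stage/sample/library gets its
# own reproducible stream; stays below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.double(seed) + h) %% 2147483647)
}
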