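#' Methylotyping pipeline configuration
#'
#' Thresholds of the CREAM calling pipeline. Defaults follow the published
#' protocol: alignments kept at MAPQ >= 20, samples excluded below 100,000
#' reads on average per library, loci kept when at least half of the samples
#' reach 20X insert coverage.
#'
#' @param mapq_min Minimum mapping quality (inclusive).
#' @param nm_max Maximum edit distance (NM) per read.
#' @param min_reads_per_library Sample-exclusion threshold on the mean read
#'   count over the two libraries (inclusive).
#' @param cov_min Minimum per-sample insert coverage at a locus (inclusive).
#' @param min_sample_fraction Fraction of samples that must reach `cov_min`
#'   for a locus to be kept, in (0, 1].
#' @param presence_min Minimum insert support for a library to count as
#'   present in a sample at a locus. Not stated by the protocol; the default
#'   suppresses stray mismapped pairs at 30X depth.
#' @param end_slop Tolerance in bp when comparing insert end coordinates.
#'   0 for exact restriction-anchored ends (error-free alignments); 2-3 bp
#'   is recommended for real aligner output.
#' @param check_boundaries Verify that each insert abuts an anchor cut on
#'   one end and a CCGG cut on the other in the reference (requires the
#'   genome). Recommended for real data; off by default for simulator
#'   alignments whose coordinates are exact by construction.
#' @return A list of class `cream_pipeline_config`.
#' @export
pipeline_config <- function(mapq_min = 20, nm_max = 5,
                            min_reads_per_library = 1e5,
                            cov_min = 20, min_sample_fraction = 0.5,
                            presence_min = 5, end_slop = 0,
                            check_boundaries = FALSE) {
  cfg <- list(
    mapq_min = mapq_min, nm_max = nm_max,
    min_reads_per_library = min_reads_per_library,
    cov_min = cov_min, min_sample_fraction = min_sample_fraction,
    presence_min = presence_min, end_slop = end_slop,
    check_boundaries = isTRUE(check_boundaries)
  )
  nums <- c("mapq_min", "nm_max", "min_reads_per_library", "cov_min",
            "presence_min", "end_slop")
  for (f in nums) if (cfg[[f]] < 0) abort(paste0("`", f, "` must be >= 0."))
  if (cfg$min_sample_fraction <= 0 || cfg$min_sample_fraction > 1) {
    abort("`min_sample_fraction` must lie in (0, 1].")
  }
  structure(cfg, class = "cream_pipeline_config")
}
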