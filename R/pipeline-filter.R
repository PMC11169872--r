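FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' Filter paired-end alignments for methylotyping
#'
#' Retains primary, properly paired alignments with mapping quality at or
#' above `mapq_min`, at most `nm_max` mismatches, and the mate on the same
#' chromosome (inserts are undefined across chromosomes). Records with a
#' missing NM tag are kept and counted.
#'
#' @param records Alignment tibble (see [read_alignments()]).
#' @param config A [pipeline_config()].
#' @return The retained records, with a `counts` attribute reporting how
#'   many records each rule removed.
#' @export
filter_alignments <- function(records, config = pipeline_config()) {
  f <- records$flag
  primary <- bitwAnd(f, FLAG_SECONDARY) == 0L & bitwAnd(f, FLAG_SUPPLEMENTARY) == 0L
  paired <- bitwAnd(f, FLAG_PAIRED) > 0L
  proper <- bitwAnd(f, FLAG_PROPER) > 0L
  mapq_ok <- !is.na(records$mapq) & records$mapq >= config$mapq_min
  nm_ok <- is.na(records$nm) | records$nm <= config$nm_max
  same_chrom <- !is.na(records$mate_chrom) &
    (records$mate_chrom == records$chrom | records$mate_chrom == "=")
  keep <- primary & paired & proper & mapq_ok & nm_ok & same_chrom
  counts <- c(
    input = nrow(records),
    not_primary = sum(!primary), not_paired = sum(!paired),
    not_proper = sum(!proper), low_mapq = sum(!mapq_ok),
    high_nm = sum(!nm_ok), mate_other_chrom = sum(!same_chrom),
    nm_missing = sum(is.na(records$nm)),
    retained = sum(keep)
  )
  out <- records[keep, ]
  attr(out, "counts") <- counts
  out
}

#' Exclude low-yield samples
#'
#' A sample is excluded when its read count, averaged over the MspI and
#' HpaII libraries, falls below `min_reads_per_library` (boundary
#' inclusive). A sample missing one library contributes 0 reads for it.
#'
#' @param read_counts Tibble `sample`, `library`, `n_reads` (raw read
#'   counts per library, before filtering).
#' @param config A [pipeline_config()].
#' @return Tibble `sample`, `mean_reads`, `retained`.
#' @export
exclude_low_yield_samples <- function(read_counts, config = pipeline_config()) {
  full <- tidyr::expand_grid(sample = unique(read_counts$sample),
                             library = c("MspI", "HpaII"))
  filled <- left_join(full, read_counts, by = c("sample", "library"))
  if (anyNA(filled$n_reads)) {
    miss <- filled[is.na(filled$n_reads), ]
    warn(paste0("Missing library for sample(s): ",
                paste(unique(miss$sample), collapse = ", "),
                "; counted as 0 reads."))
    filled$n_reads[is.na(filled$n_reads)] <- 0
  }
  filled |>
    group_by(.data$sample) |>
    summarise(mean_reads = mean(.data$n_reads), .groups = "drop") |>
    mutate(retained = .data$mean_reads >= config$min_reads_per_library)
}
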