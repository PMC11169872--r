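#' Call population loci from pooled inserts
#'
#' A single left-to-right sweep per chromosome merges every set of inserts
#' (any sample, any library) sharing at least one nucleotide of overlap into
#' one locus spanning the leftmost to the rightmost position. Loci are typed
#' `overlapping` when both libraries contribute inserts, otherwise
#' `msp_only` or `hpa_only`.
#'
#' @param inserts Insert tibble pooled across samples.
#' @return List with `loci` (tibble `locus_id`, `chrom`, `start`, `end`,
#'   `type`, `n_inserts`) and `inserts` (the input with `locus_id`
#'   attached).
#' @export
call_loci <- function(inserts) {
  if (nrow(inserts) == 0) {
    return(list(
      loci = tibble(locus_id = integer(0), chrom = character(0),
                    start = integer(0), end = integer(0), type = character(0),
                    n_inserts = integer(0)),
      inserts = mutate(inserts, locus_id = integer(0))
    ))
  }
  ins <- arrange(inserts, .data$chrom, .data$start, .data$end)
  ins <- ins |>
    group_by(.data$chrom) |>
    mutate(
      run_end = cummax(dplyr::lag(.data$end, default = dplyr::first(.data$start))),
      new_locus = .data$start >= .data$run_end | row_number() == 1L
    ) |>
    ungroup() |>
    mutate(locus_id = cumsum(.data$new_locus)) |>
    select(-"run_end", -"new_locus")

  loci <- ins |>
    group_by(.data$locus_id) |>
    summarise(
      chrom = first(.data$chrom), start = min(.data$start), end = max(.data$end),
      type = if (dplyr::n_distinct(.data$library) == 2L) "overlapping"
             else if (first(.data$library) == "MspI") "msp_only" else "hpa_only",
      n_inserts = n(), .groups = "drop"
    )
  list(loci = loci, inserts = ins)
}

#' Coverage filter over called loci
#'
#' A locus is retained when at least `min_sample_fraction` of the samples
#' (rounded up) have a summed insert support of `cov_min` or more across the
#' two libraries. This keeps loci with population-wide coverage and removes
#' those confidently observed in only a few samples.
#'
#' @param called Result of [call_loci()].
#' @param n_samples Number of samples in the analysis (after sample
#'   exclusion); defaults to the samples seen among the inserts.
#' @param config A [pipeline_config()].
#' @return The `called` list restricted to retained loci, with a
#'   `dropped_loci` element recording removals.
#' @export
coverage_filter <- function(called, n_samples = NULL, config = pipeline_config()) {
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(called$inserts$sample)
  if (n_samples == 0) abort("Zero samples.")
  need <- ceiling(config$min_sample_fraction * n_samples)
  per_sample <- called$inserts |>
    group_by(.data$locus_id, .data$sample) |>
    summarise(cov = sum(.data$support), .groups = "drop")
  ok <- per_sample |>
    group_by(.data$locus_id) |>
    summarise(n_ok = sum(.data$cov >= config$cov_min), .groups = "drop") |>
    filter(.data$n_ok >= need)
  keep <- called$loci$locus_id %in% ok$locus_id
  list(
    loci = called$loci[keep, ],
    inserts = filter(called$inserts, .data$locus_id %in% ok$locus_id),
    dropped_loci = called$loci[!keep, ]
  )
}
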