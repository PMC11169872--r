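norm_methylomes <- function(methylomes) {
  if (is.list(methylomes) && !is.data.frame(methylomes) && !is.null(methylomes$methylomes)) {
    methylomes <- methylomes$methylomes
  }
  stopifnot(all(c("sample", "chrom", "pos") %in% names(methylomes)))
  methylomes
}

#' Ground-truth methylation status per capturable locus and sample
#'
#' Digests the genome in silico with both libraries for every sample and
#' records, for each anchor-adjacent region that passes size selection in at
#' least one library state, the comparative outcome: `A` (identical fragment
#' in both libraries, unmethylated), `B` (MspI only), `C` (both present with
#' different lengths), `D` (HpaII only). Regions are keyed by the anchor cut
#' coordinate and the side of the fragment it terminates, which is invariant
#' to methylation state.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param methylomes Output of [simulate_methylomes()], or a tibble with
#'   columns `sample`, `chrom`, `pos`.
#' @param config A [sim_config()] (size-selection window).
#' @return Tibble with one row per capturable (region, sample): `chrom`,
#'   `anchor_pos`, `anchor_end`, `start`, `end` (union of the observed
#'   fragment intervals), `sample`, `msp_start`, `msp_end`, `hpa_start`,
#'   `hpa_end` (NA when that library's fragment is not selected) and
#'   `status`.
#' @export
ground_truth <- function(genome, methylomes, config) {
  genome <- as_genome(genome)
  methylomes <- norm_methylomes(methylomes)
  samples <- unique(methylomes$sample)

  anchors <- enzyme_by_name(c("NsiI", "PstI"))
  anchor_cuts <- cut_table(genome, anchors, "anchor")
  ccgg <- find_sites_set(genome, "CCGG")
  ccgg_key <- paste(ccgg$chrom, ccgg$pos)
  ccgg_cuts <- tibble(chrom = ccgg$chrom, cut = ccgg$pos + 1L,
                      enzyme = "HpaII", role = "cutter")

  # MspI digestion ignores methylation, so it is shared by all samples
  msp <- fragments_from_cuts(bind_rows(
    anchor_cuts, mutate(ccgg_cuts, enzyme = "MspI"))) |>
    size_select(config$size_min, config$size_max) |>
    annotate_anchor() |>
    select("chrom", "anchor_pos", "anchor_end",
           msp_start = "start", msp_end = "end")

  meth_by_sample <- split(paste(methylomes$chrom, methylomes$pos), methylomes$sample)
  per_sample <- lapply(samples, function(s) {
    blocked <- ccgg_key %in% meth_by_sample[[s]]
    hpa <- fragments_from_cuts(bind_rows(anchor_cuts, ccgg_cuts[!blocked, ])) |>
      size_select(config$size_min, config$size_max) |>
      annotate_anchor() |>
      select("chrom", "anchor_pos", "anchor_end",
             hpa_start = "start", hpa_end = "end")
    full_join(msp, hpa, by = c("chrom", "anchor_pos", "anchor_end")) |>
      mutate(sample = s)
  })

  bind_rows(per_sample) |>
    mutate(
      status = dplyr::case_when(
        !is.na(.data$msp_start) & !is.na(.data$hpa_start) &
          .data$msp_start == .data$hpa_start & .data$msp_end == .data$hpa_end ~ "A",
        !is.na(.data$msp_start) & is.na(.data$hpa_start) ~ "B",
        is.na(.data$msp_start) & !is.na(.data$hpa_start) ~ "D",
        TRUE ~ "C"
      ),
      start = pmin(.data$msp_start, .data$hpa_start, na.rm = TRUE),
      end = pmax(.data$msp_end, .data$hpa_end, na.rm = TRUE)
    ) |>
    select("chrom", "anchor_pos", "anchor_end", "start", "end", "sample",
           "msp_start", "msp_end", "hpa_start", "hpa_end", "status") |>
    arrange(.data$chrom, .data$anchor_pos, .data$anchor_end, .data$sample)
}
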