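as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (length(genome) > 0 && is.null(names(genome))) {
      abort("Genome sequences must be named.")
    }
    return(genome)
  }
  if (is.character(genome)) {
    if (length(genome) > 0 && is.null(names(genome))) {
      abort("Genome sequences must be named.")
    }
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("`genome` must be a named character vector or a DNAStringSet.")
}

empty_fragments <- function() {
  tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    length = integer(0), left_enzyme = character(0), right_enzyme = character(0)
  )
}

# all top-strand cut coordinates for one enzyme set on a genome
# role labels anchors vs the CCGG cutter so fragment ends can be typed
cut_table <- function(genome, enzymes, role, methylome = NULL) {
  rows <- lapply(seq_len(nrow(enzymes)), function(i) {
    sites <- find_sites_set(genome, enzymes$motif[i])
    if (enzymes$methylation_sensitive[i] && !is.null(methylome) && nrow(methylome) > 0) {
      sites <- anti_join(sites, methylome[c("chrom", "pos")], by = c("chrom", "pos"))
    }
    sites$cut <- sites$pos + enzymes$cut_offset[i]
    sites$enzyme <- enzymes$name[i]
    sites
  })
  out <- bind_rows(rows)
  out$role <- role
  out[c("chrom", "cut", "enzyme", "role")]
}

#' In-silico double digestion into a CREAM library
#'
#' Cuts the genome at every anchor-enzyme site and at every CCGG site the
#' cutter can act on: a methylation-sensitive cutter (HpaII) skips CCGG sites
#' whose motif start is recorded as methylated, while MspI cuts regardless.
#' Fragments are the intervals between consecutive cut coordinates; only
#' fragments with exactly one anchor-derived end and one cutter-derived end
#' enter the library, mirroring the adapter chemistry (a barcoded adapter on
#' the anchor overhang, a common adapter on the CCGG overhang).
#'
#' Coordinates are 0-based half-open; a cut is the single top-strand
#' coordinate `motif start + cut_offset` and sticky-end overhangs are ignored
#' for length bookkeeping (at most a 4 bp effect).
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param methylome Tibble with columns `chrom`, `pos`: 0-based starts of
#'   methylated CCGG motifs. `NULL` means no methylation.
#' @param anchors Character vector of anchor enzyme names from
#'   [cream_enzymes()], or a tibble of enzymes.
#' @param cutter Cutter enzyme name (`"MspI"` or `"HpaII"`) or a one-row
#'   enzyme tibble.
#' @return Tibble of fragments: `chrom`, `start`, `end` (0-based half-open),
#'   `length`, `left_enzyme`, `right_enzyme`.
#' @examples
#' g <- c(chr1 = paste0(
#'   strrep("A", 10), "ATGCAT", strrep("T", 284), "CCGG", strrep("A", 60)))
#' digest_library(g, cutter = "MspI")
#' @export
digest_library <- function(genome, methylome = NULL, anchors = c("NsiI", "PstI"),
                           cutter = "MspI") {
  genome <- as_genome(genome)
  if (length(genome) == 0) return(empty_fragments())
  anchors <- if (is.character(anchors)) enzyme_by_name(anchors) else anchors
  cutter <- if (is.character(cutter)) enzyme_by_name(cutter) else cutter
  if (nrow(cutter) != 1L) abort("Exactly one cutter enzyme is required.")

  cuts <- bind_rows(
    cut_table(genome, anchors, "anchor"),
    cut_table(genome, cutter, "cutter", methylome = methylome)
  )
  fragments_from_cuts(cuts)
}

# intervals between consecutive cuts on each chromosome, restricted to
# fragments with exactly one anchor end and one cutter end
fragments_from_cuts <- function(cuts) {
  if (nrow(cuts) == 0) return(empty_fragments())
  # deterministic priority if two enzymes ever cut the same coordinate
  cuts <- cuts |>
    arrange(.data$chrom, .data$cut, .data$role) |>
    distinct(.data$chrom, .data$cut, .keep_all = TRUE)

  cuts |>
    group_by(.data$chrom) |>
    mutate(
      start = .data$cut, end = lead(.data$cut),
      left_enzyme = .data$enzyme, right_enzyme = lead(.data$enzyme),
      left_role = .data$role, right_role = lead(.data$role)
    ) |>
    ungroup() |>
    filter(!is.na(.data$end),
           (.data$left_role == "anchor") != (.data$right_role == "anchor")) |>
    mutate(length = .data$end - .data$start) |>
    select("chrom", "start", "end", "length", "left_enzyme", "right_enzyme")
}

# which end of each anchored fragment carries the anchor cut, and where
annotate_anchor <- function(fragments, anchor_names = c("NsiI", "PstI")) {
  fragments |>
    mutate(
      anchor_end = if_else(.data$left_enzyme %in% anchor_names, "left", "right"),
      anchor_pos = if_else(.data$anchor_end == "left", .data$start, .data$end)
    )
}

#' Size-select fragments
#'
#' Retains fragments whose length lies in the inclusive window
#' `[min_len, max_len]`, emulating the 200-400 bp capture step performed
#' before sequencing.
#'
#' @param fragments Tibble with a `length` column (as from [digest_library()]).
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered tibble, order preserved.
#' @export
size_select <- function(fragments, min_len = 200, max_len = 400) {
  if (min_len < 0 || max_len < 0) abort("Size bounds must be non-negative.")
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  filter(fragments, .data$length >= min_len, .data$length <= max_len)
}
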