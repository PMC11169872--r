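#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition motif, the offset of
#' the top-strand cut from the motif start, and whether cutting is blocked by
#' full methylation of the CpG inside the motif. CREAM libraries combine two
#' rare-cutting anchor enzymes (NsiI, PstI) with one of the CCGG isoschizomers:
#' MspI (insensitive) or HpaII (blocked at a methylated CCGG).
#'
#' @param name Enzyme name.
#' @param motif Recognition motif over A/C/G/T.
#' @param cut_offset Bases from the motif start to the top-strand cut,
#'   in `[0, nchar(motif)]`.
#' @param methylation_sensitive `TRUE` if the enzyme is blocked when the CpG
#'   of its motif is fully methylated.
#' @return A one-row tibble with columns `name`, `motif`, `cut_offset`,
#'   `methylation_sensitive`.
#' @examples
#' restriction_enzyme("MspI", "CCGG", 1, FALSE)
#' @export
restriction_enzyme <- function(name, motif, cut_offset, methylation_sensitive) {
  motif <- toupper(motif)
  if (!nzchar(motif) || nchar(motif) < 4L) {
    abort("`motif` must have at least 4 bases.")
  }
  if (grepl("[^ACGT]", motif)) {
    abort("`motif` must contain only A, C, G, T.")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(motif)) {
    abort("`cut_offset` must lie within [0, nchar(motif)].")
  }
  tibble(
    name = as.character(name), motif = motif, cut_offset = cut_offset,
    methylation_sensitive = isTRUE(methylation_sensitive)
  )
}

#' Built-in CREAM enzyme catalog
#'
#' The four enzymes of the CREAM protocol: the six-cutter anchors NsiI
#' (ATGCA/T) and PstI (CTGCA/G), and the CCGG isoschizomers MspI (C/CGG,
#' methylation-insensitive) and HpaII (C/CGG, blocked by CpG methylation).
#'
#' @return A tibble with one row per enzyme.
#' @examples
#' cream_enzymes()
#' @export
cream_enzymes <- function() {
  bind_rows(
    restriction_enzyme("NsiI",  "ATGCAT", 5L, FALSE),
    restriction_enzyme("PstI",  "CTGCAG", 5L, FALSE),
    restriction_enzyme("MspI",  "CCGG",   1L, FALSE),
    restriction_enzyme("HpaII", "CCGG",   1L, TRUE)
  )
}

enzyme_by_name <- function(names) {
  cat <- cream_enzymes()
  missing <- setdiff(names, cat$name)
  if (length(missing)) abort(paste0("Unknown enzyme(s): ", paste(missing, collapse = ", ")))
  cat[match(names, cat$name), ]
}

#' Locate all occurrences of a motif in a sequence
#'
#' Exhaustive scan, overlapping occurrences allowed; `N` (or any non-ACGT
#' character) never matches.
#'
#' @param sequence A DNA string over A/C/G/T/N, or a `Biostrings::DNAString`.
#' @param motif Motif over A/C/G/T.
#' @return Integer vector of 0-based motif start positions, strictly
#'   increasing.
#' @examples
#' find_sites("ACCGGT", "CCGG")
#' @export
find_sites <- function(sequence, motif) {
  if (!nzchar(motif)) abort("`motif` must be non-empty.")
  subject <- if (is(sequence, "DNAString")) sequence else Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(subject) < nchar(motif)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(toupper(motif)), subject, fixed = TRUE)
  as.integer(BiocGenerics::start(m)) - 1L
}

# vectorised over a DNAStringSet; returns tibble(chrom, pos) of 0-based starts
find_sites_set <- function(genome, motif) {
  hits <- Biostrings::vmatchPattern(Biostrings::DNAString(motif), genome, fixed = TRUE)
  tibble(
    chrom = rep(names(genome), S4Vectors::elementNROWS(hits)),
    pos = unlist(lapply(hits, BiocGenerics::start), use.names = FALSE) - 1L
  )
}

#' GC content of a motif
#'
#' @param motif Motif over A/C/G/T, non-empty.
#' @return Fraction of G/C bases in `[0, 1]`.
#' @examples
#' gc_content("CCGG")   # 1
#' gc_content("ATGCAT") # 1/3
#' @export
gc_content <- function(motif) {
  motif <- toupper(motif)
  if (!nzchar(motif)) abort("`motif` must be non-empty.")
  if (grepl("[^ACGT]", motif)) abort("`motif` must contain only A, C, G, T.")
  bases <- strsplit(motif, "")[[1]]
  mean(bases %in% c("G", "C"))
}

#' Expected spacing between restriction sites
#'
#' Under an i.i.d. base model with the given per-base probabilities, the
#' expected number of base pairs between successive occurrences of `motif`
#' is `1 / prod(p(base_i))`. On uniform random DNA a six-cutter such as NsiI
#' cuts every 4^6 = 4096 bp.
#'
#' @param motif Motif over A/C/G/T.
#' @param base_probs Named numeric vector of base probabilities for A, C, G,
#'   T; non-negative, summing to 1. Default uniform.
#' @return Expected spacing in bp; `Inf` if any motif base has probability 0.
#' @examples
#' expected_cut_spacing("ATGCAT") # 4096
#' @export
expected_cut_spacing <- function(motif, base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  motif <- toupper(motif)
  if (!nzchar(motif)) abort("`motif` must be non-empty.")
  if (grepl("[^ACGT]", motif)) abort("`motif` must contain only A, C, G, T.")
  if (any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-8) {
    abort("`base_probs` must be non-negative and sum to 1.")
  }
  p <- base_probs[strsplit(motif, "")[[1]]]
  if (any(is.na(p))) abort("`base_probs` must be named with A, C, G, T.")
  if (any(p == 0)) return(Inf)
  1 / prod(p)
}

#' Expected spacing between cuts of a combined set of anchor enzymes
#'
#' Site-occurrence rates add under the i.i.d. model, so the expected spacing
#' between cuts by any of the motifs is the harmonic combination
#' `1 / sum(1 / spacing_m)`. Combining NsiI and PstI halves the 4096 bp
#' single-enzyme spacing to 2048 bp, anchoring fragments twice as densely.
#' Assumes no motif occurs inside another.
#'
#' @param motifs Character vector of distinct motifs.
#' @inheritParams expected_cut_spacing
#' @return Expected spacing in bp between cuts by any motif.
#' @examples
#' combined_anchor_spacing(c("ATGCAT", "CTGCAG")) # 2048
#' @export
combined_anchor_spacing <- function(motifs, base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(motifs) == 0) abort("`motifs` must be non-empty.")
  spacings <- vapply(motifs, expected_cut_spacing, numeric(1), base_probs = base_probs)
  1 / sum(1 / spacings)
}
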