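#' Simulate sequencing of one sample library
#'
#' Digests the genome with the requested library (MspI or HpaII, honouring
#' the sample's methylome), applies size selection, samples each selected
#' fragment `Poisson(depth)` times and emits one proper paired-end alignment
#' per copy: read 1 covers the fragment start forward, read 2 the fragment
#' end on the reverse strand, both of length `min(read_length, fragment
#' length)`. Alignments are exact by construction (MAPQ 60, proper-pair
#' flags); substitution errors, when requested, are recorded in the `NM`
#' field and applied to the emitted sequence.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param methylome Tibble `chrom`, `pos` of methylated CCGG starts for this
#'   sample (ignored by the MspI library).
#' @param config A [sim_config()].
#' @param library `"MspI"` or `"HpaII"`.
#' @param sample_id Sample identifier recorded in the output.
#' @param emit_seq If `TRUE`, attach the read sequence (reference
#'   orientation) with substitution errors applied; needed to write SAM or
#'   FASTQ.
#' @return Tibble of alignment records, two rows per pair: `qname`,
#'   `sample`, `library`, `chrom`, `pos`, `end` (0-based half-open), `mapq`,
#'   `flag`, `cigar`, `mate_chrom`, `mate_pos`, `tlen`, `nm`, `as`, and
#'   `seq` when `emit_seq`.
#' @export
simulate_reads <- function(genome, methylome, config, library = c("MspI", "HpaII"),
                           sample_id = "S01", emit_seq = FALSE) {
  stopifnot(inherits(config, "cream_sim_config"))
  library <- match.arg(library)
  genome <- as_genome(genome)
  set.seed(derive_seed(config$seed, paste0("reads_", sample_id, "_", library)))

  frags <- digest_library(genome, methylome = methylome, cutter = library) |>
    size_select(config$size_min, config$size_max)
  if (nrow(frags) == 0 || config$depth == 0) return(empty_records(emit_seq))

  copies <- rpois(nrow(frags), config$depth)
  frags <- frags[rep.int(seq_len(nrow(frags)), copies), ]
  if (nrow(frags) == 0) return(empty_records(emit_seq))

  rl <- pmin(config$read_length, frags$length)
  qname <- sprintf("%s_%s_%07d", sample_id, library, seq_len(nrow(frags)))

  r1 <- tibble(
    qname = qname, sample = sample_id, library = library,
    chrom = frags$chrom, pos = frags$start, end = frags$start + rl,
    mapq = 60L, flag = 99L, cigar = paste0(rl, "M"),
    mate_chrom = frags$chrom, mate_pos = frags$end - rl,
    tlen = frags$length
  )
  r2 <- tibble(
    qname = qname, sample = sample_id, library = library,
    chrom = frags$chrom, pos = frags$end - rl, end = frags$end,
    mapq = 60L, flag = 147L, cigar = paste0(rl, "M"),
    mate_chrom = frags$chrom, mate_pos = frags$start,
    tlen = -frags$length
  )
  recs <- bind_rows(r1, r2)

  if (emit_seq) {
    recs$seq <- extract_ref_seq(genome, recs$chrom, recs$pos, recs$end)
    err <- apply_substitutions(recs$seq, config$substitution_error_rate)
    recs$seq <- err$seq
    recs$nm <- err$nm
  } else {
    width <- recs$end - recs$pos
    recs$nm <- if (config$substitution_error_rate > 0) {
      rbinom(nrow(recs), width, config$substitution_error_rate)
    } else {
      integer(nrow(recs))
    }
  }
  recs$as <- (recs$end - recs$pos) - recs$nm
  arrange(recs, .data$chrom, .data$pos, .data$qname)
}

empty_records <- function(emit_seq = FALSE) {
  out <- tibble(
    qname = character(0), sample = character(0), library = character(0),
    chrom = character(0), pos = integer(0), end = integer(0),
    mapq = integer(0), flag = integer(0), cigar = character(0),
    mate_chrom = character(0), mate_pos = integer(0), tlen = integer(0),
    nm = integer(0), as = integer(0)
  )
  if (emit_seq) out$seq <- character(0)
  out
}

# reference-orientation substrings, vectorised per chromosome
extract_ref_seq <- function(genome, chrom, start, end) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    ss <- Biostrings::extractAt(genome[[cn]], IRanges::IRanges(start[i] + 1L, end[i]))
    out[i] <- as.character(ss)
  }
  out
}

# i.i.d. substitution errors; returns modified sequences and per-read counts
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(list(seq = seqs, nm = integer(length(seqs))))
  widths <- nchar(seqs)
  nm <- rbinom(length(seqs), widths, rate)
  hit <- which(nm > 0)
  for (i in hit) {
    pos <- sample.int(widths[i], nm[i])
    s <- strsplit(seqs[i], "")[[1]]
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  list(seq = seqs, nm = nm)
}
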