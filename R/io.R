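#' Read a reference genome from FASTA
#'
#' @param path FASTA file (plain or gzipped).
#' @return A named `DNAStringSet`; record names are truncated at the first
#'   whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read gene intervals from GFF3 or BED
#'
#' @param path Annotation file; `type == "gene"` records are used from GFF3.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `gene_id`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
  }
  ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$name %||%
    sprintf("gene_%05d", seq_along(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    gene_id = as.character(ids)
  )
}

#' Write gene intervals as GFF3
#' @param genes Tibble `chrom`, `start`, `end` (0-based half-open), `gene_id`.
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    type = "gene", ID = genes$gene_id, source = "cream"
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED6
#'
#' Intervals are written 0-based half-open as BED requires.
#'
#' @param x Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @param name,score Optional column names used for the BED name and score
#'   fields.
#' @export
write_bed6 <- function(x, path, name = NULL, score = NULL) {
  bed <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if (is.null(name)) "." else as.character(x[[name]]),
    score = if (is.null(score)) 0 else x[[score]],
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a sample/library manifest
#'
#' The manifest binds alignment files to samples: one row per (sample,
#' library) with columns `sample`, `library` (MspI or HpaII) and `path`.
#'
#' @param path Manifest TSV.
#' @return Validated tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "library", "path")
  if (!all(need %in% names(m))) {
    abort(paste0("Manifest must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(m$library %in% c("MspI", "HpaII"))) {
    abort("Manifest `library` must be 'MspI' or 'HpaII'.")
  }
  m
}

sam_header <- function(genome) {
  genome <- as_genome(genome)
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
}

#' Write alignment records as coordinate-sorted SAM
#'
#' @param records Alignment tibble as produced by [simulate_reads()]; a
#'   `seq` column is used when present, otherwise SEQ/QUAL are `*`.
#' @param genome Genome providing the `@SQ` header lines.
#' @param path Output SAM path.
#' @export
write_sam <- function(records, genome, path) {
  records <- arrange(records, .data$chrom, .data$pos, .data$qname, .data$flag)
  has_seq <- "seq" %in% names(records) && nrow(records) > 0
  seq <- if (has_seq) records$seq else rep("*", nrow(records))
  qual <- if (has_seq) strrep("I", nchar(records$seq)) else rep("*", nrow(records))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s\tNM:i:%d\tAS:i:%d",
    records$qname, records$flag, records$chrom, records$pos + 1L,
    records$mapq, records$cigar, records$mate_pos + 1L, records$tlen,
    seq, qual, records$nm, records$as
  )
  readr::write_lines(c(sam_header(genome), body), path)
  invisible(path)
}

#' Write paired FASTQ for a set of alignment records
#'
#' Read 2 is emitted reverse-complemented, restoring sequencing orientation
#' from the reference-orientation SAM sequence.
#'
#' @param records Alignment tibble with a `seq` column.
#' @param path_r1,path_r2 Output FASTQ paths (gzipped if ending in `.gz`).
#' @export
write_fastq_pair <- function(records, path_r1, path_r2) {
  if (!"seq" %in% names(records)) abort("Records carry no sequence; simulate with `emit_seq = TRUE`.")
  is_r1 <- bitwAnd(records$flag, 64L) > 0L
  r1 <- arrange(records[is_r1, ], .data$qname)
  r2 <- arrange(records[!is_r1, ], .data$qname)
  r2_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2$seq)))
  fq <- function(qn, sq, mate) {
    as.vector(rbind(paste0("@", qn, "/", mate), sq, "+", strrep("I", nchar(sq))))
  }
  readr::write_lines(fq(r1$qname, r1$seq, 1L), path_r1)
  readr::write_lines(fq(r2$qname, r2_seq, 2L), path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read paired-end alignments from SAM or BAM
#'
#' SAM input is converted to temporary BAM with Rsamtools before parsing, so
#' both formats are accepted everywhere.
#'
#' @param path SAM or BAM file.
#' @param sample,library Labels attached to every record.
#' @return Alignment tibble with the columns used by [filter_alignments()].
#' @export
read_alignments <- function(path, sample, library) {
  if (!file.exists(path)) abort(paste0("No such alignment file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos", "isize"),
    tag = c("NM", "AS")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0) return(empty_records())
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  tibble(
    qname = b$qname, sample = sample, library = library,
    chrom = as.character(b$rname), pos = b$pos - 1L,
    end = b$pos - 1L + width,
    mapq = as.integer(b$mapq), flag = as.integer(b$flag), cigar = b$cigar,
    mate_chrom = as.character(b$mrnm), mate_pos = b$mpos - 1L,
    tlen = as.integer(b$isize),
    nm = as.integer(b$tag$NM %||% rep(NA_integer_, n)),
    as = as.integer(b$tag$AS %||% rep(NA_integer_, n))
  )
}

#' Read all alignments referenced by a manifest
#'
#' @param manifest Tibble or path to a manifest TSV (see [read_manifest()]).
#' @return One alignment tibble, samples and libraries bound together.
#' @export
read_manifest_alignments <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  bind_rows(pmap(manifest[c("sample", "library", "path")], function(sample, library, path) {
    read_alignments(path, sample = sample, library = library)
  }))
}
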