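#' Simulate a complete CREAM experiment
#'
#' Runs the full generator: genome with genic blocks, layered clonal
#' methylomes, ground-truth status table and paired-end alignments for both
#' libraries of every sample. Optionally writes the experiment to disk as
#' FASTA, GFF3, TSV and coordinate-sorted SAM (plus FASTQ on request), in
#' which case the directory is a ready-made input for [call_methylotypes()]
#' via its manifest.
#'
#' @param config A [sim_config()].
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @param fastq Also write gzipped FASTQ when `dir` is given.
#' @param force Overwrite a non-empty existing directory.
#' @return A list of class `cream_sim`: `config`, `genome`, `genes`,
#'   `samples`, `methylomes`, `sites`, `truth`, `records` and (when written)
#'   `manifest`.
#' @export
simulate_experiment <- function(config, dir = NULL, fastq = FALSE, force = FALSE) {
  stopifnot(inherits(config, "cream_sim_config"))
  writing <- !is.null(dir)
  if (writing) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
      abort("Output directory exists and is not empty; use `force = TRUE`.")
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }

  gen <- simulate_genome(config)
  meth <- simulate_methylomes(gen$genome, config)
  truth <- ground_truth(gen$genome, meth, config)

  meth_split <- split(meth$methylomes, meth$methylomes$sample)
  recs <- vector("list", 2L * nrow(meth$samples))
  k <- 0L
  for (s in meth$samples$sample) {
    for (lib in c("MspI", "HpaII")) {
      k <- k + 1L
      recs[[k]] <- simulate_reads(
        gen$genome, meth_split[[s]], config, library = lib,
        sample_id = s, emit_seq = writing
      )
    }
  }
  records <- bind_rows(recs)

  out <- list(
    config = config, genome = gen$genome, genes = gen$genes,
    samples = meth$samples, methylomes = meth$methylomes,
    sites = meth$sites, truth = truth, records = records
  )
  class(out) <- "cream_sim"
  if (writing) out$manifest <- write_experiment(out, dir, fastq = fastq)
  out
}

#' @export
print.cream_sim <- function(x, ...) {
  cat("CREAM simulated experiment\n")
  cat(sprintf("  genome:  %d chromosome(s), %s bp total\n",
              length(x$genome), format(sum(Biostrings::width(x$genome)), big.mark = ",")))
  cat(sprintf("  samples: %d in %d line(s)\n",
              nrow(x$samples), length(unique(x$samples$line))))
  cat(sprintf("  truth:   %d (region, sample) cells over %d regions\n",
              nrow(x$truth),
              nrow(distinct(x$truth, .data$chrom, .data$anchor_pos, .data$anchor_end))))
  cat(sprintf("  reads:   %s alignment records\n",
              format(nrow(x$records), big.mark = ",")))
  invisible(x)
}

# writes every artifact of a simulated experiment; returns the run manifest
write_experiment <- function(sim, dir, fastq = FALSE) {
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3_genes(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$samples, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$methylomes, file.path(dir, "methylomes.tsv"))

  rows <- list()
  for (s in unique(sim$records$sample)) {
    for (lib in c("MspI", "HpaII")) {
      recs <- filter(sim$records, .data$sample == s, .data$library == lib)
      sam_path <- file.path(dir, sprintf("%s_%s.sam", s, lib))
      write_sam(recs, sim$genome, sam_path)
      if (fastq) {
        write_fastq_pair(recs, file.path(dir, sprintf("%s_%s_R1.fastq.gz", s, lib)),
                         file.path(dir, sprintf("%s_%s_R2.fastq.gz", s, lib)))
      }
      rows[[length(rows) + 1L]] <- tibble(sample = s, library = lib, path = sam_path)
    }
  }
  manifest <- bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
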