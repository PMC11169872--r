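#' Run the full CREAM methylotyping pipeline
#'
#' Binds the pipeline stages end to end: sample exclusion on raw read
#' yield, alignment filtering, insert reconstruction, locus calling, the
#' population coverage filter, per-sample classification and matrix
#' assembly. Accepts either an in-memory alignment tibble (e.g. from
#' [simulate_experiment()]) or a manifest of SAM/BAM files.
#'
#' @param alignments Alignment record tibble with `sample` and `library`
#'   columns, or a manifest (tibble or TSV path; see [read_manifest()]).
#' @param genome Genome (object or FASTA path); required only for the
#'   boundary-motif check and coverage statistics.
#' @param config A [pipeline_config()].
#' @return A `cream_methylotypes` object with additional elements:
#'   `inserts`, `sample_yield`, `coverage`, and `log` (per-stage counts).
#' @export
call_methylotypes <- function(alignments, genome = NULL, config = pipeline_config()) {
  if (is.character(alignments) || (is.data.frame(alignments) && "path" %in% names(alignments))) {
    alignments <- read_manifest_alignments(alignments)
  }
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  log <- list()

  yield <- alignments |> count(.data$sample, .data$library, name = "n_reads")
  excl <- exclude_low_yield_samples(yield, config)
  kept_samples <- excl$sample[excl$retained]
  if (length(kept_samples) == 0) abort("All samples excluded by the read-yield rule.")
  if (any(!excl$retained)) {
    inform(paste0("Excluded low-yield sample(s): ",
                  paste(excl$sample[!excl$retained], collapse = ", ")))
  }
  alignments <- filter(alignments, .data$sample %in% kept_samples)
  log$samples <- c(input = nrow(excl), retained = length(kept_samples))

  filtered <- filter_alignments(alignments, config)
  log$alignments <- attr(filtered, "counts")

  inserts <- reconstruct_inserts(filtered, config, genome = genome)
  log$inserts <- attr(inserts, "counts")

  called <- call_loci(inserts)
  log$loci <- c(called = nrow(called$loci))
  called <- coverage_filter(called, n_samples = length(kept_samples), config)
  log$loci <- c(log$loci, retained = nrow(called$loci),
                dropped_coverage = nrow(called$dropped_loci))

  cls <- classify_methylation(called, samples = kept_samples, config)
  res <- build_matrix(cls, called$loci, samples = kept_samples)
  res$inserts <- inserts
  res$sample_yield <- excl
  if (!is.null(genome)) res$coverage <- coverage_stats(inserts, genome)
  res$log <- log
  res
}

#' Write methylotyping results to a directory
#'
#' Emits the locus list as BED6 (name = type, score = number of methylated
#' samples), the status matrix as TSV (`A`/`B`/`C`/`D`, `AMB`, `NA`), the
#' per-locus summary, methylated/unmethylated locus BED sets and a run log.
#'
#' @param x A `cream_methylotypes` object.
#' @param dir Output directory (created if needed).
#' @export
write_methylotypes <- function(x, dir) {
  stopifnot(inherits(x, "cream_methylotypes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed6(x$loci, file.path(dir, "loci.bed"), name = "type", score = "n_methylated")
  wide <- x$calls |>
    mutate(code = dplyr::case_when(
      .data$status == "ambiguous" ~ "AMB",
      .data$status == "missing" ~ NA_character_,
      TRUE ~ as.character(.data$status)
    )) |>
    pivot_wider(id_cols = "sample", names_from = "locus_id",
                names_prefix = "locus_", values_from = "code")
  readr::write_tsv(wide, file.path(dir, "methylotype_matrix.tsv"))
  readr::write_tsv(x$loci, file.path(dir, "locus_summary.tsv"))
  for (cl in c("methylated", "unmethylated", "ambiguous")) {
    sel <- filter(x$loci, .data$locus_call == cl)
    write_bed6(sel, file.path(dir, paste0(cl, "_loci.bed")),
               name = "type", score = "n_methylated")
  }
  if (!is.null(x$log)) {
    log_lines <- unlist(lapply(names(x$log), function(nm) {
      c(paste0("[", nm, "]"),
        paste0("  ", names(x$log[[nm]]), " = ", x$log[[nm]]))
    }))
    readr::write_lines(log_lines, file.path(dir, "run_log.txt"))
  }
  invisible(dir)
}

#' Read a methylotype status matrix written by [write_methylotypes()]
#'
#' @param path `methylotype_matrix.tsv` file.
#' @return Long tibble `sample`, `locus_id`, `status`.
#' @export
read_methylotype_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    pivot_longer(-"sample", names_to = "locus_id", values_to = "code",
                 names_prefix = "locus_") |>
    mutate(
      locus_id = as.integer(.data$locus_id),
      status = factor(dplyr::case_when(
        is.na(.data$code) ~ "missing",
        .data$code == "AMB" ~ "ambiguous",
        TRUE ~ .data$code
      ), levels = STATUS_LEVELS)
    ) |>
    select("sample", "locus_id", "status")
}
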