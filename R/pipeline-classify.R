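STATUS_LEVELS <- c("A", "B", "C", "D", "ambiguous", "missing")

# greedy support-weighted merge of near-identical intervals; exact
# de-duplication when slop = 0
merge_slop <- function(starts, ends, support, slop) {
  if (slop == 0) {
    key <- paste(starts, ends)
    agg <- rowsum(support, key)
    u <- !duplicated(key)
    return(tibble(start = starts[u], end = ends[u],
                  support = as.integer(agg[match(key[u], rownames(agg))])))
  }
  ord <- order(-support, starts)
  starts <- starts[ord]; ends <- ends[ord]; support <- support[ord]
  taken <- rep(FALSE, length(starts))
  out <- list()
  for (i in seq_along(starts)) {
    if (taken[i]) next
    grp <- !taken & abs(starts - starts[i]) <= slop & abs(ends - ends[i]) <= slop
    taken[grp] <- TRUE
    out[[length(out) + 1L]] <- tibble(start = starts[i], end = ends[i],
                                      support = sum(support[grp]))
  }
  bind_rows(out)
}

#' Classify each locus per sample into the four comparative possibilities
#'
#' Applies the CREAM decision rules to the insert evidence of every
#' (locus, sample): a library is *present* when it has an insert with
#' support at or above `presence_min`. With both libraries present and equal
#' intervals (within `end_slop` at both ends) the site is unmethylated
#' (`A`); an MspI-only insert is `B`; an HpaII-only insert is `D`; both
#' present, sharing the anchor-side coordinate but differing on the CCGG
#' side, is the length shift `C`. Evidence with more than one distinct
#' interval in a library, or intervals differing at both ends, is
#' `ambiguous`; no evidence at all is `missing`.
#'
#' @param called Result of [call_loci()] (optionally after
#'   [coverage_filter()]).
#' @param samples Character vector of all samples in the analysis; every
#'   (locus, sample) combination is classified, including absent ones.
#' @param config A [pipeline_config()].
#' @return Tibble: `locus_id`, `sample`, `status`, and the per-library
#'   interval evidence (`msp_start`, `msp_end`, `msp_support`, `hpa_start`,
#'   `hpa_end`, `hpa_support`, `msp_n`, `hpa_n`).
#' @export
classify_methylation <- function(called, samples = NULL, config = pipeline_config()) {
  inserts <- called$inserts
  if (is.null(samples)) samples <- sort(unique(inserts$sample))
  ev <- filter(inserts, .data$support >= config$presence_min)

  merged <- ev |>
    group_by(.data$locus_id, .data$sample, .data$library) |>
    dplyr::reframe(merge_slop(.data$start, .data$end, .data$support, config$end_slop))
  summ <- merged |>
    group_by(.data$locus_id, .data$sample, .data$library) |>
    summarise(
      n_int = n(),
      start = first(.data$start), end = first(.data$end),
      support = sum(.data$support), .groups = "drop"
    )
  wide <- summ |>
    pivot_wider(id_cols = c("locus_id", "sample"),
                names_from = "library",
                values_from = c("n_int", "start", "end", "support"),
                values_fill = list(n_int = 0L)) |>
    ensure_cols(c("n_int_MspI", "start_MspI", "end_MspI", "support_MspI",
                  "n_int_HpaII", "start_HpaII", "end_HpaII", "support_HpaII"))

  grid <- tidyr::expand_grid(locus_id = called$loci$locus_id, sample = samples)
  wide <- left_join(grid, wide, by = c("locus_id", "sample")) |>
    mutate(across(c("n_int_MspI", "n_int_HpaII"), ~ replace_na(.x, 0L)))

  slop <- config$end_slop
  msp <- wide$n_int_MspI
  hpa <- wide$n_int_HpaII
  start_eq <- abs(wide$start_MspI - wide$start_HpaII) <= slop
  end_eq <- abs(wide$end_MspI - wide$end_HpaII) <= slop
  status <- dplyr::case_when(
    msp == 0 & hpa == 0 ~ "missing",
    msp > 1 | hpa > 1 ~ "ambiguous",
    msp == 1 & hpa == 0 ~ "B",
    msp == 0 & hpa == 1 ~ "D",
    start_eq & end_eq ~ "A",
    xor(start_eq, end_eq) ~ "C",
    TRUE ~ "ambiguous"
  )
  wide |>
    mutate(status = factor(status, levels = STATUS_LEVELS)) |>
    rename(msp_n = "n_int_MspI", msp_start = "start_MspI", msp_end = "end_MspI",
           msp_support = "support_MspI", hpa_n = "n_int_HpaII",
           hpa_start = "start_HpaII", hpa_end = "end_HpaII",
           hpa_support = "support_HpaII") |>
    select("locus_id", "sample", "status", "msp_n", "msp_start", "msp_end",
           "msp_support", "hpa_n", "hpa_start", "hpa_end", "hpa_support")
}

ensure_cols <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) {
    df[[cl]] <- if (startsWith(cl, "n_int")) 0L else NA_integer_
  }
  df
}

#' Assemble the methylotype matrix
#'
#' Combines per-(locus, sample) classifications into a samples-by-loci
#' status matrix with a binary methylated view (`B`/`C`/`D` methylated, `A`
#' unmethylated, `ambiguous`/`missing` masked) and a per-locus population
#' summary. A locus is summarised `methylated` when any sample carries a
#' methylated status (and `polymorphic` when unmethylated samples coexist),
#' `unmethylated` when every informative sample is `A`, and `ambiguous` when
#' no sample is informative -- ambiguous loci are reported, never silently
#' dropped.
#'
#' @param classifications Output of [classify_methylation()].
#' @param loci Locus tibble from [call_loci()].
#' @param samples Character vector of samples (row order of the matrix).
#' @return An object of class `cream_methylotypes`.
#' @export
build_matrix <- function(classifications, loci, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(classifications$sample))
  if (!setequal(unique(classifications$locus_id), loci$locus_id)) {
    abort("Classified loci and locus table do not match.")
  }
  calls <- classifications |>
    mutate(sample = factor(.data$sample, levels = samples)) |>
    arrange(.data$locus_id, .data$sample) |>
    mutate(sample = as.character(.data$sample))

  summary <- calls |>
    group_by(.data$locus_id) |>
    summarise(
      n_A = sum(.data$status == "A"), n_B = sum(.data$status == "B"),
      n_C = sum(.data$status == "C"), n_D = sum(.data$status == "D"),
      n_ambiguous = sum(.data$status == "ambiguous"),
      n_missing = sum(.data$status == "missing"),
      .groups = "drop"
    ) |>
    mutate(
      n_methylated = .data$n_B + .data$n_C + .data$n_D,
      locus_call = dplyr::case_when(
        .data$n_methylated > 0 ~ "methylated",
        .data$n_A > 0 ~ "unmethylated",
        TRUE ~ "ambiguous"
      ),
      polymorphic = .data$n_methylated > 0 & .data$n_A > 0
    )
  structure(
    list(calls = calls, loci = left_join(loci, summary, by = "locus_id"),
         samples = samples),
    class = "cream_methylotypes"
  )
}

#' @export
print.cream_methylotypes <- function(x, ...) {
  cat(sprintf("CREAM methylotypes: %d samples x %d loci\n",
              length(x$samples), nrow(x$loci)))
  tab <- table(factor(x$loci$locus_call, c("methylated", "unmethylated", "ambiguous")))
  cat(sprintf("  loci: %d methylated (%d polymorphic), %d unmethylated, %d ambiguous\n",
              tab[["methylated"]], sum(x$loci$polymorphic),
              tab[["unmethylated"]], tab[["ambiguous"]]))
  invisible(x)
}

#' Binary methylated view of a methylotype object
#'
#' @param x A `cream_methylotypes` object.
#' @param ... Unused.
#' @return Numeric samples-by-loci matrix: 1 methylated (B/C/D), 0
#'   unmethylated (A), `NA` for ambiguous or missing cells.
#' @export
as.matrix.cream_methylotypes <- function(x, ...) {
  bin <- dplyr::case_when(
    x$calls$status %in% c("B", "C", "D") ~ 1,
    x$calls$status == "A" ~ 0,
    TRUE ~ NA_real_
  )
  m <- matrix(NA_real_, nrow = length(x$samples), ncol = nrow(x$loci),
              dimnames = list(x$samples, paste0("locus_", x$loci$locus_id)))
  m[cbind(match(x$calls$sample, x$samples),
          match(x$calls$locus_id, x$loci$locus_id))] <- bin
  m
}

#' @describeIn build_matrix Long tidy table of per-(locus, sample) calls.
#' @param x A `cream_methylotypes` object.
#' @param ... Unused.
#' @method tidy cream_methylotypes
#' @export
tidy.cream_methylotypes <- function(x, ...) {
  x$calls |>
    left_join(select(x$loci, "locus_id", "chrom", "start", "end", "type"),
              by = "locus_id") |>
    mutate(methylated = dplyr::case_when(
      .data$status %in% c("B", "C", "D") ~ TRUE,
      .data$status == "A" ~ FALSE,
      TRUE ~ NA
    )) |>
    select("locus_id", "chrom", "start", "end", "type", "sample", "status",
           "methylated")
}

#' @describeIn build_matrix One-row summary of the matrix.
#' @method glance cream_methylotypes
#' @export
glance.cream_methylotypes <- function(x, ...) {
  tibble(
    n_samples = length(x$samples),
    n_loci = nrow(x$loci),
    n_methylated = sum(x$loci$locus_call == "methylated"),
    n_unmethylated = sum(x$loci$locus_call == "unmethylated"),
    n_ambiguous = sum(x$loci$locus_call == "ambiguous"),
    n_polymorphic = sum(x$loci$polymorphic)
  )
}
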