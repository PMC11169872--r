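#' Reconstruct sequenced inserts from read pairs
#'
#' Pairs records by query name within each (sample, library) and rebuilds
#' the original insert as the interval from the leftmost read start to the
#' rightmost read end; the unsequenced middle of long inserts is spanned by
#' the mate coordinates. Identical intervals within a (sample, library) are
#' collapsed, incrementing `support`. When `config$check_boundaries` is on
#' and a genome is supplied, inserts are dropped unless one end abuts an
#' anchor cut and the other a CCGG cut in the reference (within
#' `end_slop`) -- the check that both restriction sites are present in the
#' insert.
#'
#' @param records Filtered alignment tibble.
#' @param config A [pipeline_config()].
#' @param genome Genome for the boundary-motif check (optional).
#' @return Tibble of inserts: `sample`, `library`, `chrom`, `start`, `end`,
#'   `length`, `support`, with a `counts` attribute.
#' @export
reconstruct_inserts <- function(records, config = pipeline_config(), genome = NULL) {
  if (nrow(records) == 0) {
    out <- tibble(sample = character(0), library = character(0),
                  chrom = character(0), start = integer(0), end = integer(0),
                  length = integer(0), support = integer(0))
    attr(out, "counts") <- c(pairs = 0L, unpaired = 0L, negative = 0L,
                             boundary_fail = 0L, inserts = 0L)
    return(out)
  }
  is_r1 <- bitwAnd(records$flag, 64L) > 0L
  r1 <- records[is_r1, ]
  r2 <- records[!is_r1, ]
  key1 <- paste(r1$sample, r1$library, r1$qname)
  key2 <- paste(r2$sample, r2$library, r2$qname)
  m <- match(key1, key2)
  paired <- !is.na(m)
  unpaired <- sum(!paired) + (nrow(r2) - sum(paired))
  a <- r1[paired, ]
  b <- r2[m[paired], ]

  ins <- tibble(
    sample = a$sample, library = a$library, chrom = a$chrom,
    start = pmin(a$pos, b$pos), end = pmax(a$end, b$end)
  )
  neg <- ins$end <= ins$start
  ins <- ins[!neg, ]

  boundary_fail <- 0L
  if (config$check_boundaries && !is.null(genome)) {
    ok <- check_insert_boundaries(ins, genome, config$end_slop)
    boundary_fail <- sum(!ok)
    ins <- ins[ok, ]
  }

  out <- ins |>
    count(.data$sample, .data$library, .data$chrom, .data$start, .data$end,
          name = "support") |>
    mutate(length = .data$end - .data$start) |>
    select("sample", "library", "chrom", "start", "end", "length", "support")
  attr(out, "counts") <- c(
    pairs = sum(paired), unpaired = as.integer(unpaired),
    negative = sum(neg), boundary_fail = as.integer(boundary_fail),
    inserts = nrow(out)
  )
  out
}

# TRUE when one insert end matches an anchor cut and the other a CCGG cut
check_insert_boundaries <- function(inserts, genome, slop = 0) {
  genome <- as_genome(genome)
  anchors <- enzyme_by_name(c("NsiI", "PstI"))
  anchor_cuts <- cut_table(genome, anchors, "anchor")
  ccgg <- find_sites_set(genome, "CCGG")
  near <- function(x, chrom, cuts_tbl, cut_col = "cut") {
    ok <- logical(length(x))
    for (cn in unique(chrom)) {
      i <- which(chrom == cn)
      cuts <- sort(cuts_tbl[[cut_col]][cuts_tbl$chrom == cn])
      if (length(cuts) == 0) next
      j <- findInterval(x[i], cuts)
      lo <- ifelse(j >= 1, cuts[pmax(j, 1)], -Inf)
      hi <- ifelse(j < length(cuts), cuts[pmin(j + 1, length(cuts))], Inf)
      ok[i] <- pmin(abs(x[i] - lo), abs(hi - x[i])) <= slop
    }
    ok
  }
  ccgg_cuts <- tibble(chrom = ccgg$chrom, cut = ccgg$pos + 1L)
  s_anchor <- near(inserts$start, inserts$chrom, anchor_cuts)
  e_anchor <- near(inserts$end, inserts$chrom, anchor_cuts)
  s_ccgg <- near(inserts$start, inserts$chrom, ccgg_cuts)
  e_ccgg <- near(inserts$end, inserts$chrom, ccgg_cuts)
  (s_anchor & e_ccgg) | (s_ccgg & e_anchor)
}

#' Genome coverage and depth of the captured regions
#'
#' @param inserts Insert tibble (see [reconstruct_inserts()]).
#' @param genome Genome whose total length defines the denominator.
#' @return Tibble per library: `library`, `pct_covered` (percent of the
#'   genome under at least one insert), `mean_depth` (insert-bases per
#'   covered base; 0 with `empty = TRUE` when nothing is covered).
#' @export
coverage_stats <- function(inserts, genome) {
  genome <- as_genome(genome)
  glen <- sum(as.double(Biostrings::width(genome)))
  if (glen == 0) abort("Empty genome.")
  libs <- unique(inserts$library)
  if (length(libs) == 0) libs <- character(0)
  rows <- lapply(libs, function(lib) {
    x <- inserts[inserts$library == lib, ]
    if (nrow(x) == 0) {
      return(tibble(library = lib, pct_covered = 0, mean_depth = 0, empty = TRUE))
    }
    covered <- sum(vapply(split(x, x$chrom), function(xc) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(xc$start + 1L, xc$end))))
    }, numeric(1)))
    tibble(
      library = lib,
      pct_covered = 100 * covered / glen,
      mean_depth = sum(as.double(x$support) * (x$end - x$start)) / covered,
      empty = FALSE
    )
  })
  bind_rows(rows)
}
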