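mk_record <- function(qname, chrom = "chr1", pos = 0L, end = 150L,
                      mapq = 60L, flag = 99L, nm = 0L,
                      mate_chrom = chrom, sample = "S01", library = "MspI",
                      mate_pos = pos, tlen = 300L) {
  tibble::tibble(qname = qname, sample = sample, library = library,
                 chrom = chrom, pos = pos, end = end, mapq = mapq, flag = flag,
                 cigar = paste0(end - pos, "M"), mate_chrom = mate_chrom,
                 mate_pos = mate_pos, tlen = tlen, nm = nm, as = end - pos - nm)
}

test_that("alignment filtering applies each rule at its exact boundary", {
  recs <- dplyr::bind_rows(
    mk_record("q1"),                       # clean
    mk_record("q2", mapq = 20L),           # boundary mapq kept
    mk_record("q3", mapq = 19L),           # below mapq dropped
    mk_record("q4", nm = 5L),              # boundary nm kept
    mk_record("q5", nm = 6L),              # above nm dropped
    mk_record("q6", flag = 99L + 256L),    # secondary dropped
    mk_record("q7", flag = 99L + 2048L),   # supplementary dropped
    mk_record("q8", flag = 97L),           # not proper pair dropped
    mk_record("q9", mate_chrom = "chr2"),  # mate elsewhere dropped
    mk_record("q10", nm = NA_integer_)     # missing NM kept, counted
  )
  kept <- filter_alignments(recs, pipeline_config())
  expect_setequal(kept$qname, c("q1", "q2", "q4", "q10"))
  counts <- attr(kept, "counts")
  expect_equal(unname(counts["input"]), 10)
  expect_equal(unname(counts["retained"]), 4)
  expect_equal(unname(counts["low_mapq"]), 1)
  expect_equal(unname(counts["high_nm"]), 1)
  expect_equal(unname(counts["not_primary"]), 2)
  expect_equal(unname(counts["not_proper"]), 1)
  expect_equal(unname(counts["mate_other_chrom"]), 1)
  expect_equal(unname(counts["nm_missing"]), 1)
})

test_that("sample exclusion averages the two libraries with inclusive boundary", {
  rc <- tibble::tribble(
    ~sample, ~library, ~n_reads,
    "S01", "MspI", 150000, "S01", "HpaII", 60000,   # mean 105000 -> retained
    "S02", "MspI", 100000, "S02", "HpaII", 100000,  # boundary -> retained
    "S03", "MspI", 100000, "S03", "HpaII", 99998    # mean 99999 -> excluded
  )
  res <- exclude_low_yield_samples(rc, pipeline_config())
  expect_equal(res$retained[match(c("S01", "S02", "S03"), res$sample)],
               c(TRUE, TRUE, FALSE))
  expect_equal(res$mean_reads[res$sample == "S01"], 105000)

  # a missing library counts as zero reads and is warned about
  expect_warning(
    res2 <- exclude_low_yield_samples(rc[rc$sample != "S03" | rc$library == "MspI", ]),
    "S03"
  )
  expect_equal(res2$mean_reads[res2$sample == "S03"], 50000)
  expect_false(res2$retained[res2$sample == "S03"])
})

test_that("inserts span the outermost read coordinates and collapse by support", {
  pair <- function(qname, start, end, sample = "S01", library = "MspI") {
    dplyr::bind_rows(
      mk_record(qname, pos = start, end = start + 150L, flag = 99L,
                sample = sample, library = library),
      mk_record(qname, pos = end - 150L, end = end, flag = 147L,
                sample = sample, library = library)
    )
  }
  recs <- dplyr::bind_rows(
    pair("a1", 100L, 400L), pair("a2", 100L, 400L), pair("a3", 100L, 400L),
    pair("b1", 1000L, 1220L),
    pair("c1", 5000L, 5300L, library = "HpaII"),
    mk_record("orphan", pos = 9000L, end = 9150L, flag = 99L)
  )
  ins <- reconstruct_inserts(recs, pipeline_config())
  expect_equal(nrow(ins), 3L)
  first <- ins[ins$start == 100, ]
  expect_equal(first$end, 400L)
  expect_equal(first$length, 300L)
  expect_equal(first$support, 3L)
  expect_equal(ins$support[ins$start == 1000], 1L)
  counts <- attr(ins, "counts")
  expect_equal(unname(counts["pairs"]), 5)
  expect_equal(unname(counts["unpaired"]), 1)
  # short inserts where the reads overlap still reconstruct exactly
  short <- reconstruct_inserts(pair("s1", 200L, 410L), pipeline_config())
  expect_equal(short$length, 210L)
})

test_that("the boundary check keeps inserts flanked by anchor and CCGG cuts", {
  s <- strrep("A", 1000)
  substr(s, 101, 106) <- "ATGCAT"   # cut at 105
  substr(s, 401, 404) <- "CCGG"     # cut at 401
  g <- c(chr1 = s)
  ins <- tibble::tibble(
    sample = "S01", library = "MspI", chrom = "chr1",
    start = c(105L, 105L, 200L), end = c(401L, 390L, 401L)
  )
  ok <- cream:::check_insert_boundaries(ins, g, slop = 0)
  expect_equal(ok, c(TRUE, FALSE, FALSE))
  ok5 <- cream:::check_insert_boundaries(ins, g, slop = 15)
  expect_equal(ok5, c(TRUE, TRUE, FALSE))
})

test_that("locus calling merges 1-bp overlaps but not abutting inserts", {
  ins <- tibble::tibble(
    sample = "S01", library = c("MspI", "MspI", "HpaII", "MspI"),
    chrom = "chr1",
    start = c(0L, 99L, 150L, 300L), end = c(100L, 200L, 260L, 380L),
    length = c(100L, 101L, 110L, 80L), support = 10L
  )
  called <- call_loci(ins)
  expect_equal(nrow(called$loci), 2L)
  expect_equal(called$loci$start, c(0L, 300L))
  expect_equal(called$loci$end, c(260L, 380L))
  expect_equal(called$loci$type, c("overlapping", "msp_only"))
  expect_equal(called$loci$n_inserts, c(3L, 1L))
  # half-open intervals: [0,100) and [100,200) share no base
  abut <- dplyr::mutate(ins[1:2, ], start = c(0L, 100L), end = c(100L, 200L))
  expect_equal(nrow(call_loci(abut)$loci), 2L)
})

test_that("locus membership matches the transitive-closure oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 60
    starts <- sample.int(3000, n)
    ins <- tibble::tibble(
      sample = "S01", library = sample(c("MspI", "HpaII"), n, replace = TRUE),
      chrom = "chr1", start = starts,
      end = starts + sample(20:300, n, replace = TRUE), support = 5L
    ) |> dplyr::mutate(length = end - start)
    got <- call_loci(ins)$inserts
    got <- got[order(got$start, got$end, got$library), ]
    want <- naive_locus_closure(got$start, got$end)
    # same partition: equal membership up to relabelling
    expect_equal(match(got$locus_id, unique(got$locus_id)),
                 match(want, unique(want)))
  }
})

test_that("the coverage filter requires 20X in at least half of the samples", {
  ins <- tidyr::expand_grid(sample = c("S01", "S02", "S03", "S04"),
                            chrom = "chr1") |>
    dplyr::mutate(library = "MspI", start = 100L, end = 350L, length = 250L,
                  support = c(25L, 30L, 5L, 0L))
  called <- call_loci(ins)
  expect_equal(nrow(coverage_filter(called, 4, pipeline_config())$loci), 1L)

  weak <- dplyr::mutate(ins, support = c(25L, 5L, 5L, 0L))
  filt <- coverage_filter(call_loci(weak), 4, pipeline_config())
  expect_equal(nrow(filt$loci), 0L)
  expect_equal(nrow(filt$dropped_loci), 1L)

  # two libraries of the same sample sum toward the 20X requirement
  two_lib <- dplyr::bind_rows(ins, dplyr::mutate(ins, library = "HpaII"))
  split_cov <- dplyr::mutate(two_lib, support = rep(c(12L, 12L, 2L, 0L), 2))
  expect_equal(nrow(coverage_filter(call_loci(split_cov), 4)$loci), 1L)

  # raising cov_min can only drop loci
  set.seed(41)
  rand <- tidyr::expand_grid(sample = sprintf("S%02d", 1:6), locus = 1:20) |>
    dplyr::mutate(library = "MspI", chrom = "chr1",
                  start = locus * 1000L, end = locus * 1000L + 250L,
                  length = 250L, support = rpois(dplyr::n(), 18)) |>
    dplyr::select(-locus)
  called_rand <- call_loci(rand)
  kept_n <- vapply(c(5, 15, 20, 25), function(cm) {
    nrow(coverage_filter(called_rand, 6, pipeline_config(cov_min = cm))$loci)
  }, numeric(1))
  expect_true(all(diff(kept_n) <= 0))
})

mk_called <- function(ev) {
  # ev: tibble sample, library, start, end, support (single locus on chr1)
  ins <- dplyr::mutate(ev, chrom = "chr1", length = end - start, locus_id = 1L)
  list(
    loci = tibble::tibble(locus_id = 1L, chrom = "chr1",
                          start = min(ev$start), end = max(ev$end),
                          type = "overlapping", n_inserts = nrow(ev)),
    inserts = ins
  )
}

test_that("classification reproduces the four comparative outcomes", {
  cfg <- pipeline_config()
  ev_A <- tibble::tibble(sample = "S01", library = c("MspI", "HpaII"),
                         start = 100L, end = 350L, support = 30L)
  expect_equal(as.character(classify_methylation(mk_called(ev_A), "S01", cfg)$status), "A")

  ev_B <- ev_A[1, ]
  expect_equal(as.character(classify_methylation(mk_called(ev_B), "S01", cfg)$status), "B")

  ev_D <- ev_A[2, ]
  expect_equal(as.character(classify_methylation(mk_called(ev_D), "S01", cfg)$status), "D")

  # C: anchor-side start shared, CCGG side shifted outward in HpaII
  ev_C <- tibble::tibble(sample = "S01", library = c("MspI", "HpaII"),
                         start = 100L, end = c(350L, 390L), support = 30L)
  got_C <- classify_methylation(mk_called(ev_C), "S01", cfg)
  expect_equal(as.character(got_C$status), "C")
  expect_equal(got_C$msp_end, 350L)
  expect_equal(got_C$hpa_end, 390L)

  # two distinct MspI intervals in one sample: ambiguous
  ev_amb <- tibble::tibble(sample = "S01", library = c("MspI", "MspI"),
                           start = c(100L, 120L), end = c(350L, 380L),
                           support = 30L)
  expect_equal(as.character(classify_methylation(mk_called(ev_amb), "S01", cfg)$status),
               "ambiguous")

  # intervals differing at both ends: ambiguous, not C
  ev_both <- tibble::tibble(sample = "S01", library = c("MspI", "HpaII"),
                            start = c(100L, 110L), end = c(350L, 390L),
                            support = 30L)
  expect_equal(as.character(classify_methylation(mk_called(ev_both), "S01", cfg)$status),
               "ambiguous")

  # a second sample with no evidence at this locus is missing
  got2 <- classify_methylation(mk_called(ev_A), c("S01", "S02"), cfg)
  expect_equal(as.character(got2$status[got2$sample == "S02"]), "missing")
})

test_that("presence requires the minimum insert support", {
  ev <- tibble::tibble(sample = "S01", library = c("MspI", "HpaII"),
                       start = 100L, end = 350L, support = c(30L, 4L))
  got <- classify_methylation(mk_called(ev), "S01", pipeline_config())
  expect_equal(as.character(got$status), "B")
  ev$support <- c(30L, 5L)  # boundary: presence_min = 5 is inclusive
  got <- classify_methylation(mk_called(ev), "S01", pipeline_config())
  expect_equal(as.character(got$status), "A")
})

test_that("end_slop tolerates small boundary wobble when comparing libraries", {
  ev <- tibble::tibble(sample = "S01", library = c("MspI", "HpaII"),
                       start = c(100L, 102L), end = c(350L, 349L), support = 30L)
  expect_equal(as.character(classify_methylation(mk_called(ev), "S01",
                                                 pipeline_config())$status),
               "ambiguous")
  expect_equal(as.character(classify_methylation(mk_called(ev), "S01",
                                                 pipeline_config(end_slop = 3))$status),
               "A")
})

test_that("random evidence is always classified, matching an independent rule oracle", {
  set.seed(51)
  cfg <- pipeline_config()
  for (rep in 1:200) {
    k <- sample(0:4, 1)
    ev <- tibble::tibble(
      sample = "S01",
      library = sample(c("MspI", "HpaII"), k, replace = TRUE),
      start = sample(c(100L, 105L), k, replace = TRUE),
      end = sample(c(350L, 390L), k, replace = TRUE),
      support = sample(c(3L, 5L, 30L), k, replace = TRUE)
    ) |> dplyr::filter(end > start)
    if (nrow(ev) == 0) {
      ev <- tibble::tibble(sample = "S01", library = "MspI",
                           start = 100L, end = 350L, support = 1L)
    }
    got <- as.character(classify_methylation(mk_called(ev), "S01", cfg)$status)

    # independent restatement of the decision rules
    pres <- ev[ev$support >= cfg$presence_min, ]
    ints <- function(lib) unique(pres[pres$library == lib, c("start", "end")])
    mi <- ints("MspI"); hi <- ints("HpaII")
    want <- if (nrow(mi) == 0 && nrow(hi) == 0) "missing"
      else if (nrow(mi) > 1 || nrow(hi) > 1) "ambiguous"
      else if (nrow(hi) == 0) "B"
      else if (nrow(mi) == 0) "D"
      else if (mi$start == hi$start && mi$end == hi$end) "A"
      else if (xor(mi$start == hi$start, mi$end == hi$end)) "C"
      else "ambiguous"
    expect_equal(got, want)
  }
})

test_that("the methylotype matrix summarises loci and masks uninformative cells", {
  cls <- tibble::tibble(
    locus_id = rep(1:3, each = 3),
    sample = rep(c("S01", "S02", "S03"), 3),
    status = factor(c("A", "A", "A",
                      "B", "A", "missing",
                      "ambiguous", "missing", "missing"),
                    levels = cream:::STATUS_LEVELS),
    msp_n = 1L, msp_start = NA_integer_, msp_end = NA_integer_,
    msp_support = NA_integer_, hpa_n = 1L, hpa_start = NA_integer_,
    hpa_end = NA_integer_, hpa_support = NA_integer_
  )
  loci <- tibble::tibble(locus_id = 1:3, chrom = "chr1",
                         start = c(0L, 1000L, 2000L), end = c(300L, 1300L, 2300L),
                         type = "overlapping", n_inserts = 3L)
  x <- build_matrix(cls, loci, c("S01", "S02", "S03"))
  expect_s3_class(x, "cream_methylotypes")
  expect_equal(x$loci$locus_call, c("unmethylated", "methylated", "ambiguous"))
  expect_equal(x$loci$polymorphic, c(FALSE, TRUE, FALSE))

  m <- as.matrix(x)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(m[, 1]), c(0, 0, 0))
  expect_equal(unname(m[, 2]), c(1, 0, NA))
  expect_true(all(is.na(m[, 3])))

  td <- tidy(x)
  expect_equal(nrow(td), 9L)
  expect_equal(td$methylated[td$locus_id == 2 & td$sample == "S01"], TRUE)
  gl <- glance(x)
  expect_equal(gl$n_loci, 3L)
  expect_equal(gl$n_methylated, 1L)
  expect_equal(gl$n_polymorphic, 1L)
  expect_output(print(x), "3 samples x 3 loci")
})

test_that("coverage statistics report covered fraction and depth arithmetic", {
  g <- c(chr1 = strrep("A", 1000))
  ins <- tibble::tibble(
    sample = "S01", library = "MspI", chrom = "chr1",
    start = c(0L, 50L, 500L), end = c(100L, 150L, 700L),
    length = c(100L, 100L, 200L), support = c(2L, 1L, 1L)
  )
  cs <- coverage_stats(ins, g)
  # union [0,150) + [500,700) = 350 bases of 1000
  expect_equal(cs$pct_covered, 35)
  expect_equal(cs$mean_depth, (2 * 100 + 100 + 200) / 350)
  empty <- coverage_stats(ins[0, ] |> dplyr::mutate(library = character(0)), g)
  expect_equal(nrow(empty), 0L)
})

test_that("the orchestrator reproduces its parts on a toy experiment", {
  sim <- simulate_experiment(toy_simulation(seed = 42, n_samples = 3))
  res <- call_methylotypes(sim$records, genome = sim$genome,
                           config = pipeline_config(min_reads_per_library = 0))
  expect_s3_class(res, "cream_methylotypes")
  expect_gt(nrow(res$loci), 0)
  expect_setequal(res$samples, sim$samples$sample)
  # every call belongs to a retained locus
  expect_true(all(res$calls$locus_id %in% res$loci$locus_id))
  # the run log records the stage counts
  expect_named(res$log, c("samples", "alignments", "inserts", "loci"))
  expect_equal(unname(res$log$samples["retained"]), nrow(sim$samples))
})
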