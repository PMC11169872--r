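# Lazily built full-scale simulated experiment (the study conditions:
# 2 lines x 10 samples, 2 x 5 Mb genome, depth 30, error-free), shared by the
# end-to-end recovery, spectrum, PCA and density tests. Built once per run.
.sim_cache <- new.env(parent = emptyenv())

study_simulation <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 1)
    .sim_cache$sim <- simulate_experiment(cfg)
    .sim_cache$result <- call_methylotypes(
      .sim_cache$sim$records, genome = .sim_cache$sim$genome,
      config = pipeline_config(min_reads_per_library = 0)
    )
  }
  list(sim = .sim_cache$sim, result = .sim_cache$result)
}

# map each ground-truth region to the pipeline locus containing the base
# adjacent to its anchor cut (inside every fragment of that region)
map_truth_to_loci <- function(truth, loci) {
  truth$point <- ifelse(truth$anchor_end == "left", truth$anchor_pos,
                        truth$anchor_pos - 1L)
  loci <- loci[order(loci$chrom, loci$start), ]
  m <- rep(NA_integer_, nrow(truth))
  for (cn in unique(loci$chrom)) {
    li <- loci[loci$chrom == cn, ]
    ti <- which(truth$chrom == cn)
    j <- findInterval(truth$point[ti], li$start)
    jj <- pmax(j, 1L)
    ok <- j >= 1L & truth$point[ti] < li$end[jj]
    m[ti[ok]] <- li$locus_id[jj[ok]]
  }
  truth$locus_id <- m
  truth
}

# a tiny deterministic experiment for fast unit tests
toy_simulation <- function(seed = 42, n_samples = 3, chrom_length = 150000) {
  sim_config(n_chrom = 1, chrom_length = chrom_length, n_lines = 2,
             n_samples = n_samples, seed = seed)
}
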