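# Independent oracles used to check the package's implementations.
# These deliberately use naive algorithms, not the code paths under test.

random_dna <- function(n, gc = 0.5, with_n = FALSE) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  alphabet <- c("A", "C", "G", "T")
  if (with_n) {
    p <- c(p * 0.98, 0.02)
    alphabet <- c(alphabet, "N")
  }
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# position-by-position window comparison
naive_find_sites <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  windows <- substring(sequence, starts, starts + m - 1L)
  starts[windows == motif] - 1L
}

# enumerate-all-cuts digestion oracle: naive window scan (overlap-aware),
# explicit sort, explicit fragment walk keeping anchor+cutter fragments
naive_digest <- function(seq_chr, methylated_pos = integer(0),
                         cutter_sensitive = FALSE) {
  cuts <- data.frame(pos = integer(0), role = character(0), enz = character(0))
  for (e in list(c("ATGCAT", 5, "NsiI"), c("CTGCAG", 5, "PstI"))) {
    s <- naive_find_sites(seq_chr, e[1])
    if (length(s)) {
      cuts <- rbind(cuts, data.frame(pos = s + as.integer(e[2]),
                                     role = "anchor", enz = e[3]))
    }
  }
  cc <- naive_find_sites(seq_chr, "CCGG")
  if (cutter_sensitive) cc <- setdiff(cc, methylated_pos)
  if (length(cc)) {
    cuts <- rbind(cuts, data.frame(pos = cc + 1L, role = "cutter",
                                   enz = if (cutter_sensitive) "HpaII" else "MspI"))
  }
  cuts <- cuts[order(cuts$pos), ]
  cuts <- cuts[!duplicated(cuts$pos), ]
  out <- NULL
  if (nrow(cuts) >= 2) {
    for (i in seq_len(nrow(cuts) - 1L)) {
      if (cuts$role[i] != cuts$role[i + 1L]) {
        out <- rbind(out, data.frame(
          start = cuts$pos[i], end = cuts$pos[i + 1L],
          left_enzyme = cuts$enz[i], right_enzyme = cuts$enz[i + 1L]
        ))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      left_enzyme = character(0), right_enzyme = character(0))
  }
  out
}

# transitive closure of pairwise >=1 bp overlap, by repeated sweeps
naive_locus_closure <- function(starts, ends) {
  n <- length(starts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && starts[i] < ends[j] && starts[j] < ends[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Kruskal-Wallis H by explicit midranks and tie correction
oracle_kruskal <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ss <- tapply(r, groups, function(x) sum(x)^2 / length(x))
  H <- 12 / (N * (N + 1)) * sum(ss) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(H = H, p = stats::pchisq(H, nlevels(groups) - 1, lower.tail = FALSE))
}

# Spearman as Pearson on midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact hypergeometric upper tail by summing the pmf from choose()
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
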