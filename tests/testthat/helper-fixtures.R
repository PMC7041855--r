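# Shared fixtures: tiny designs, runs, and independent oracles.

# k amplicons on one chromosome, single gene and pool
tiny_design <- function(k = 5, chrom = "chr1", gene = "G1", pool = NULL) {
  amplicon_design(id = sprintf("%s_a%d", gene, seq_len(k)),
                  chrom = rep(chrom, k),
                  start = 1000 * seq_len(k), end = 1000 * seq_len(k) + 100,
                  gene = rep(gene, k), pool = pool)
}

# stack several tiny designs (distinct genes/chromosomes)
multi_design <- function(sizes, chroms = paste0("chr", seq_along(sizes))) {
  parts <- Map(function(k, ch, g) {
    data.frame(id = sprintf("%s_a%d", g, seq_len(k)), chrom = ch,
               start = 1000 * seq_len(k), end = 1000 * seq_len(k) + 100,
               gene = g, stringsAsFactors = FALSE)
  }, sizes, chroms, sprintf("G%d", seq_along(sizes)))
  df <- do.call(rbind, parts)
  amplicon_design(df$id, df$chrom, df$start, df$end, df$gene)
}

# run_matrix straight from a counts matrix
run_from_counts <- function(design, counts, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  vectors <- stats::setNames(lapply(seq_len(ncol(counts)),
                                    function(j) counts[, j]), sample_ids)
  assemble_run(design, vectors)
}

# status table from hand-set states (z/p only filled where needed)
status_from_states <- function(design, states, z = NULL) {
  data.frame(id = design$id, chrom = design$chrom,
             nrc = rep(1, nrow(design)),
             z = if (is.null(z)) rep(0, nrow(design)) else z,
             p = 0.5, state = states, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for call_segments: enumerate every window
# of every length >= min_amplicons over the non-missing amplicons of each
# chromosome, keep windows that are uniformly DEL or DUP, and retain the
# maximal ones.
oracle_segments <- function(states, chroms, min_amplicons) {
  keep <- list()
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch & states != "MISSING")
    n <- length(idx)
    wins <- list()
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (b - a + 1 < min_amplicons || b < a) next
      st <- states[idx[a:b]]
      if (all(st == "DEL") || all(st == "DUP"))
        wins[[length(wins) + 1]] <- list(a = a, b = b, dir = st[1])
    }
    for (w in wins) {
      maximal <- !any(vapply(wins, function(v)
        v$dir == w$dir && v$a <= w$a && v$b >= w$b &&
          (v$b - v$a) > (w$b - w$a), TRUE))
      if (maximal)
        keep[[length(keep) + 1]] <-
          list(ids = idx[w$a:w$b], dir = w$dir, chrom = ch)
    }
  }
  keep
}
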