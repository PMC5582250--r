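# Shared fixtures and independent oracles used across the suite.

rand_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1)
  paste(v, collapse = "")
}

# brute-force homology oracle: double loop over all windows and both strands
brute_scan <- function(queries, ests, max_mismatches) {
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qv <- strsplit(queries$seq[qi], "")[[1]]
    ql <- length(qv)
    for (ei in seq_len(nrow(ests))) {
      ev <- strsplit(ests$seq[ei], "")[[1]]
      L <- length(ev)
      if (ql > L) next
      for (s in 1:(L - ql + 1)) {
        w <- ev[s:(s + ql - 1)]
        mm_f <- sum(w != qv | w == "N" | qv == "N")
        if (mm_f <= max_mismatches) {
          out[[length(out) + 1]] <- paste(queries$id[qi], ests$id[ei], "+",
                                          s, s + ql - 1, mm_f)
        }
        wr <- rev(chartr("ACGUN", "UGCAN", w))
        mm_r <- sum(wr != qv | wr == "N" | qv == "N")
        if (mm_r <= max_mismatches) {
          out[[length(out) + 1]] <- paste(queries$id[qi], ests$id[ei], "-",
                                          s, s + ql - 1, mm_r)
        }
      }
    }
  }
  sort(unlist(out))
}

hit_keys <- function(hits) {
  sort(paste(hits$query_id, hits$est_id, hits$strand, hits$est_start,
             hits$est_end, hits$mismatches))
}

# a small EST set with planted near-matches of the given queries
planted_est_set <- function(queries, n_ests, est_len = 90, max_sub = 5) {
  ids <- paste0("e", seq_len(n_ests))
  seqs <- vapply(seq_len(n_ests), function(i) {
    base <- rand_rna(est_len)
    qi <- sample(nrow(queries), 1)
    k <- sample(0:max_sub, 1)
    ins <- mutate_seq(queries$seq[qi], if (k > 0)
      sample(nchar(queries$seq[qi]), k) else integer(0))
    if (runif(1) < 0.5) ins <- revcomp(ins)
    pos <- sample(seq_len(est_len - nchar(ins)), 1)
    paste0(substr(base, 1, pos), ins,
           substr(base, pos + 1, est_len - nchar(ins)))
  }, character(1))
  seq_set(ids, seqs)
}

# bases that would pair (WC or wobble) with `base`
pairing_partners_for_test <- function(base) {
  switch(base, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
}

random_query_set <- function(n, len = 20:22) {
  seq_set(sprintf("tst-miR%03d", seq_len(n)),
          vapply(seq_len(n), function(i) rand_rna(sample(len, 1)), ""))
}
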