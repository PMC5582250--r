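#' Collapse exact-duplicate mature miRNA probes
#'
#' Mature miRNAs are strongly conserved across plant species, so a probe
#' set pooled from many species contains many identical residue strings.
#' Exact duplicates are collapsed to a single query; the representative is
#' the lexicographically smallest id and the ids of merged members are
#' retained in an `aliases` column (comma-separated).
#'
#' @param queries a `seq_set` of mature miRNA probes (RNA, 18-26 nt).
#' @return a `seq_set` with one row per unique residue string, plus
#'   `aliases` and `family` columns.
#' @export
dereplicate_queries <- function(queries) {
  stopifnot(nrow(queries) > 0)
  sp <- split(queries$id, queries$seq)
  reps <- vapply(sp, function(ids) sort(ids)[1], character(1))
  # preserve first-appearance order of each unique sequence
  first_pos <- vapply(names(sp), function(s) min(which(queries$seq == s)),
                      integer(1))
  ord <- order(first_pos)
  seqs <- names(sp)[ord]
  ids <- reps[ord]
  aliases <- vapply(sp[ord], function(x) paste(sort(x), collapse = ","),
                    character(1))
  out <- seq_set(id = unname(ids), seq = seqs, moltype = "RNA")
  out$aliases <- unname(aliases)
  out$family <- mirna_family(out$id)
  out
}

#' Scan ESTs for homologues of mature miRNA probes
#'
#' Reports every window, on both strands of every EST, whose Hamming
#' distance to a probe is at most `max_mismatches` (ungapped comparison;
#' `N` in a window never matches and counts as a mismatch).  This exact
#' scan replaces a heuristic seeded search: for ungapped matches within a
#' small substitution budget it is strictly more sensitive.  Coordinates
#' are 1-based inclusive on the plus strand of the EST; for minus-strand
#' hits `matched_subsequence` is the reverse complement of the plus-strand
#' window, i.e. the string that was compared with the probe.
#'
#' @param queries dereplicated `seq_set` of probes (see
#'   [dereplicate_queries()]); a `family` column is carried through if
#'   present.
#' @param ests `seq_set` of EST sequences.
#' @param max_mismatches substitution budget (default 4).
#' @return data.frame of hits: `query_id`, `family`, `est_id`, `strand`,
#'   `est_start`, `est_end`, `mismatches`, `matched_subsequence`.
#' @export
scan_homology <- function(queries, ests, max_mismatches = 4) {
  fam <- if (!is.null(queries$family)) queries$family else mirna_family(queries$id)
  est_rna <- chartr("T", "U", toupper(ests$seq))
  subjects_fwd <- Biostrings::DNAStringSet(chartr("U", "T", est_rna))
  subjects_rev <- Biostrings::reverseComplement(subjects_fwd)
  est_len <- nchar(ests$seq)
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- chartr("U", "T", queries$seq[qi])
    qlen <- nchar(q)
    pat <- Biostrings::DNAString(q)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") subjects_fwd else subjects_rev
      mm <- Biostrings::vmatchPattern(pat, subj,
                                      max.mismatch = max_mismatches,
                                      fixed = TRUE)
      for (ei in seq_along(mm)) {
        r <- mm[[ei]]
        if (length(r) == 0) next
        st <- IRanges::start(r); en <- IRanges::end(r)
        keep <- st >= 1 & en <= est_len[ei]
        st <- st[keep]; en <- en[keep]
        if (!length(st)) next
        win <- as.character(Biostrings::extractAt(
          subj[[ei]], IRanges::IRanges(st, en)))
        nmm <- vapply(win, function(w) hamming(chartr("T", "U", w),
                                               queries$seq[qi]), integer(1))
        keep2 <- nmm <= max_mismatches
        if (!any(keep2)) next
        st <- st[keep2]; en <- en[keep2]; win <- win[keep2]; nmm <- nmm[keep2]
        if (strand == "-") {
          L <- est_len[ei]
          plus_start <- L - en + 1
          plus_end <- L - st + 1
        } else {
          plus_start <- st
          plus_end <- en
        }
        out[[length(out) + 1]] <- data.frame(
          query_id = queries$id[qi], family = fam[qi], est_id = ests$id[ei],
          strand = strand, est_start = plus_start, est_end = plus_end,
          mismatches = nmm,
          matched_subsequence = chartr("T", "U", unname(win)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), family = character(0),
                      est_id = character(0), strand = character(0),
                      est_start = integer(0), est_end = integer(0),
                      mismatches = integer(0),
                      matched_subsequence = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$est_id, res$est_start, res$strand, res$query_id), ]
  rownames(res) <- NULL
  res
}

#' Hamming distance between equal-length strings
#'
#' `N` at any position counts as a mismatch (it matches nothing).
#'
#' @param a,b strings of equal length.
#' @return integer distance.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

#' Collapse redundant hits from near-identical ESTs
#'
#' ESTs sampled from the same gene appear under multiple accessions.  For
#' every hit the surrounding region (hit plus 200 nt of flank each side) is
#' extracted; regions sharing at least `identity_threshold` alignment
#' identity over at least 90 percent mutual length overlap are clustered by
#' single linkage, and one representative hit is kept per cluster: the one
#' from the longest source EST, ties broken by the lexicographically
#' smallest EST id.  Hits of different probe families are never merged.
#'
#' @param hits data.frame from [scan_homology()].
#' @param ests `seq_set` the hits refer to.
#' @param identity_threshold identity fraction for clustering (default 0.95).
#' @param flank context taken around each hit, nt (default 200).
#' @return filtered hits data.frame (one representative per cluster).
#' @export
collapse_redundant <- function(hits, ests, identity_threshold = 0.95,
                               flank = 200) {
  if (nrow(hits) == 0) return(hits)
  est_seq <- setNames(ests$seq, ests$id)
  est_len <- setNames(nchar(ests$seq), ests$id)
  regions <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- max(1, hits$est_start[i] - flank)
    e <- min(est_len[[hits$est_id[i]]], hits$est_end[i] + flank)
    reg <- substr(est_seq[[hits$est_id[i]]], s, e)
    if (hits$strand[i] == "-") reg <- revcomp(reg)
    regions[i] <- reg
  }
  n <- nrow(hits)
  # single-linkage clustering on the identity graph, within probe family
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (hits$family[i] != hits$family[j]) next
      li <- nchar(regions[i]); lj <- nchar(regions[j])
      if (min(li, lj) / max(li, lj) < 0.9) next
      al <- pairwise_align(regions[i], regions[j])
      if (al$identity >= identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  cl <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(cl)) {
    members <- which(cl == g)
    lens <- est_len[hits$est_id[members]]
    best <- members[order(-lens, hits$est_id[members])][1]
    keep[best] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
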