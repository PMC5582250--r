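#' Longest open reading frame across all six frames
#'
#' ESTs are single-pass fragments, so an ORF may be truncated at either
#' end: reading frames are scanned for stop-free codon runs, and within
#' each run the ORF starts at the first AUG, or at the run's first codon
#' when the run begins at the sequence edge (5'-truncated CDS).  The ORF
#' ends at the stop codon or at the edge.  Lengths are in amino acids,
#' excluding the stop.
#'
#' @param est a single-row `seq_set` slice, or a list/row with `id` and
#'   `seq`, or a plain sequence string.
#' @return list of class `orf_call`: `est_id`, `frame` (+1,+2,+3,-1,-2,-3),
#'   `orf_start`, `orf_end` (1-based nt on the plus strand of the EST) and
#'   `orf_aa_len`.
#' @export
longest_orf <- function(est) {
  if (is.character(est)) est <- list(id = "seq", seq = est)
  s <- chartr("T", "U", toupper(est$seq[1]))
  n <- nchar(s)
  best <- list(est_id = est$id[1], frame = 1L, orf_start = NA_integer_,
               orf_end = NA_integer_, orf_aa_len = 0L)
  for (dir in c(1L, -1L)) {
    seq_dir <- if (dir == 1L) s else revcomp(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      codons <- substring(seq_dir, off + 1 + 3 * (0:(ncod - 1)),
                          off + 3 + 3 * (0:(ncod - 1)))
      is_stop <- codons %in% c("UAA", "UAG", "UGA")
      is_start <- codons == "AUG"
      run_start <- 1L
      k <- 1L
      while (k <= ncod + 1L) {
        if (k > ncod || is_stop[k]) {
          # run of stop-free codons [run_start, k-1]
          if (k - 1L >= run_start) {
            cand_start <- NA_integer_
            if (run_start == 1L) {
              cand_start <- run_start  # open at the edge
            } else {
              aug <- which(is_start[run_start:(k - 1L)])
              if (length(aug)) cand_start <- run_start + aug[1] - 1L
            }
            if (!is.na(cand_start)) {
              aa <- k - cand_start   # codons up to (not incl.) stop/edge
              if (aa > best$orf_aa_len) {
                nt_start <- off + 3L * (cand_start - 1L) + 1L
                nt_end <- off + 3L * (k - 1L)
                if (dir == -1L) {
                  tmp <- n - nt_end + 1L
                  nt_end <- n - nt_start + 1L
                  nt_start <- tmp
                }
                best <- list(est_id = est$id[1],
                             frame = dir * (off + 1L),
                             orf_start = nt_start, orf_end = nt_end,
                             orf_aa_len = as.integer(aa))
              }
            }
          }
          run_start <- k + 1L
        }
        k <- k + 1L
      }
    }
  }
  class(best) <- "orf_call"
  best
}

#' Classify an EST as protein-coding by ORF length
#'
#' A database-free coding filter: an EST is called protein-coding when its
#' longest six-frame ORF reaches `min_orf_aa` amino acids.  Users with a
#' real protein-homology screen can instead supply a precomputed exclusion
#' list to [filter_coding()].
#'
#' @param est sequence record or string (see [longest_orf()]).
#' @param min_orf_aa calling threshold in amino acids (default 80).
#' @return list with `coding` (logical) and `orf` (the [longest_orf()]
#'   call backing the verdict).
#' @export
is_protein_coding <- function(est, min_orf_aa = 80) {
  orf <- longest_orf(est)
  list(coding = orf$orf_aa_len >= min_orf_aa, orf = orf)
}

#' Remove protein-coding ESTs from a collection
#'
#' @param ests `seq_set` of ESTs.
#' @param min_orf_aa ORF threshold, amino acids (default 80).
#' @param exclude_ids optional character vector of EST ids to drop
#'   unconditionally (e.g. from an external protein-homology search); these
#'   bypass the ORF rule.
#' @return list with `ests` (the retained `seq_set`) and `excluded`
#'   (data.frame of dropped ids with ORF evidence: frame, coordinates,
#'   amino-acid length; NA evidence for list-based exclusions).
#' @export
filter_coding <- function(ests, min_orf_aa = 80, exclude_ids = NULL) {
  drop <- logical(nrow(ests))
  ev <- vector("list", nrow(ests))
  for (i in seq_len(nrow(ests))) {
    if (!is.null(exclude_ids) && ests$id[i] %in% exclude_ids) {
      drop[i] <- TRUE
      ev[[i]] <- data.frame(est_id = ests$id[i], reason = "exclude_list",
                            frame = NA_integer_, orf_start = NA_integer_,
                            orf_end = NA_integer_, orf_aa_len = NA_integer_,
                            stringsAsFactors = FALSE)
      next
    }
    call <- is_protein_coding(ests[i, ], min_orf_aa)
    if (call$coding) {
      drop[i] <- TRUE
      o <- call$orf
      ev[[i]] <- data.frame(est_id = o$est_id, reason = "orf",
                            frame = o$frame, orf_start = o$orf_start,
                            orf_end = o$orf_end, orf_aa_len = o$orf_aa_len,
                            stringsAsFactors = FALSE)
    }
  }
  excluded <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(excluded)) {
    excluded <- data.frame(est_id = character(0), reason = character(0),
                           frame = integer(0), orf_start = integer(0),
                           orf_end = integer(0), orf_aa_len = integer(0),
                           stringsAsFactors = FALSE)
  }
  kept <- ests[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(ests = kept, excluded = excluded)
}
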