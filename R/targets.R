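#' Score an aligned miRNA/target-site duplex
#'
#' The two strings must be equal-length aligned sequences: the miRNA 5'->3'
#' and the target site 3'->5', so that column *i* pairs miRNA position *i*.
#' Per column the penalty is 0 for a Watson-Crick pair, 0.5 for a G:U
#' wobble, 1.0 for a mismatch and 2.0 for a gap (`-` in either string);
#' penalties are doubled when the column's miRNA position lies in the seed
#' region (positions 2-13; a column that is a gap in the miRNA is
#' attributed to the next miRNA position).  The expectation is the sum.
#'
#' @param mirna aligned miRNA string (5'->3', `-` for gaps).
#' @param site aligned site string (3'->5', `-` for gaps).
#' @param seed_start,seed_end seed region bounds in miRNA coordinates
#'   (defaults 2 and 13).
#' @return list with `expectation` and `annotation` (per column: `|` WC,
#'   `o` G:U, space mismatch, `-` gap).
#' @examples
#' score_duplex("UGACAGAAGAGAGUGAGCACA", "ACUGUCUUCUCUCACUCGUGU")
#' @export
score_duplex <- function(mirna, site, seed_start = 2, seed_end = 13) {
  mv <- strsplit(toupper(chartr("T", "U", mirna)), "")[[1]]
  sv <- strsplit(toupper(chartr("T", "U", site)), "")[[1]]
  if (length(mv) != length(sv))
    stop("aligned strings must have equal length")
  ok <- c("A", "C", "G", "U", "N", "-")
  if (any(!mv %in% ok) || any(!sv %in% ok))
    stop("illegal character in aligned duplex")
  pos <- 0
  total <- 0
  ann <- character(length(mv))
  L <- sum(mv != "-")
  for (k in seq_along(mv)) {
    if (mv[k] != "-") pos <- pos + 1
    p_eff <- if (mv[k] == "-") min(pos + 1, L) else pos
    mult <- if (p_eff >= seed_start && p_eff <= seed_end) 2 else 1
    if (mv[k] == "-" || sv[k] == "-") {
      total <- total + 2 * mult
      ann[k] <- "-"
    } else {
      st <- duplex_pair_status(mv[k], sv[k])
      total <- total + c(0, 0.5, 1)[st + 1] * mult
      ann[k] <- c("|", "o", " ")[st + 1]
    }
  }
  list(expectation = total, annotation = paste(ann, collapse = ""))
}

duplex_pair_status <- function(m, t) {
  if ((m == "A" && t == "U") || (m == "U" && t == "A") ||
      (m == "G" && t == "C") || (m == "C" && t == "G")) return(0L)
  if ((m == "G" && t == "U") || (m == "U" && t == "G")) return(1L)
  2L
}

#' Find miRNA target sites in transcripts
#'
#' Slides every window of length |miRNA| +/- `max_gaps` over each
#' transcript, computes the optimal (minimum-expectation) alignment with at
#' most `max_gaps` gaps under the [score_duplex()] penalty scheme, and
#' reports every site with expectation at or below `max_expectation`.
#' Overlapping reported sites within a transcript are deduplicated to the
#' best-scoring one (ties: smaller start, then shorter site).
#'
#' @param mirna miRNA sequence (RNA string, or single-row `seq_set`).
#' @param transcripts `seq_set` of candidate target transcripts.
#' @param max_expectation reporting cutoff (default 3.0).
#' @param max_gaps gap budget per duplex (default 1).
#' @param seed_start,seed_end seed region in miRNA coordinates (2-13).
#' @return data.frame of class `target_sites`: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (1-based on the transcript), `expectation`,
#'   `mode` (`cleavage` or `translation`), `mirna_aln`, `site_aln`,
#'   `annotation`.
#' @export
find_sites <- function(mirna, transcripts, max_expectation = 3.0,
                       max_gaps = 1, seed_start = 2, seed_end = 13) {
  if (is.data.frame(mirna)) {
    mid <- mirna$id[1]; mseq <- mirna$seq[1]
  } else {
    mid <- "mirna"; mseq <- mirna
  }
  mseq <- normalize_residues(mseq, "RNA")
  stopifnot(nrow(transcripts) > 0)
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tx <- normalize_residues(transcripts$seq[ti], "RNA")
    hits <- c_scan_transcript(mseq, tx, as.integer(max_gaps),
                              max_expectation, as.integer(seed_start),
                              as.integer(seed_end))
    if (nrow(hits) == 0) next
    # deduplicate overlapping sites: best expectation, then leftmost/shortest
    ord <- order(hits$expectation, hits$site_start,
                 hits$site_end - hits$site_start)
    hits <- hits[ord, , drop = FALSE]
    keep <- rep(FALSE, nrow(hits))
    for (k in seq_len(nrow(hits))) {
      overlaps <- any(keep &
                        hits$site_start <= hits$site_end[k] &
                        hits$site_end >= hits$site_start[k])
      if (!overlaps) keep[k] <- TRUE
    }
    hits <- hits[keep, , drop = FALSE]
    hits$mirna_id <- mid
    hits$transcript_id <- transcripts$id[ti]
    out[[length(out) + 1]] <- hits
  }
  if (!length(out)) {
    res <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0), mode = character(0),
                      mirna_aln = character(0), site_aln = character(0),
                      annotation = character(0), stringsAsFactors = FALSE)
    class(res) <- c("target_sites", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  res$mode <- vapply(seq_len(nrow(res)), function(k) {
    call_mode(res[k, ])
  }, character(1))
  res <- res[, c("mirna_id", "transcript_id", "site_start", "site_end",
                 "expectation", "mode", "mirna_aln", "site_aln",
                 "annotation")]
  res <- res[order(res$transcript_id, res$site_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("target_sites", "data.frame")
  res
}

#' Call the repression mode of a target site
#'
#' Plant miRNAs usually act by transcript cleavage; imperfect pairing at
#' the duplex centre redirects repression to translational inhibition.  A
#' site is called `translation` iff any non-Watson-Crick column (mismatch,
#' G:U or gap) falls at miRNA positions 10 or 11, `cleavage` otherwise.
#'
#' @param site one row of a [find_sites()] table (needs `mirna_aln` and
#'   `annotation`).
#' @param central_positions miRNA positions defining the duplex centre
#'   (default `c(10, 11)`).
#' @return `"cleavage"` or `"translation"`.
#' @export
call_mode <- function(site, central_positions = c(10, 11)) {
  mv <- strsplit(site$mirna_aln[1], "")[[1]]
  ann <- strsplit(site$annotation[1], "")[[1]]
  pos <- cumsum(mv != "-")
  L <- max(pos)
  p_eff <- ifelse(mv == "-", pmin(pos + 1, L), pos)
  central <- p_eff %in% central_positions
  if (any(central & ann != "|")) "translation" else "cleavage"
}

#' Render target-site duplexes as a text report
#'
#' @param sites a [find_sites()] table.
#' @return character vector of report lines (also usable with
#'   [writeLines()]).
#' @export
format_duplexes <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    c(sprintf("%s -> %s [%d-%d]  expectation %.1f  %s",
              s$mirna_id, s$transcript_id, s$site_start, s$site_end,
              s$expectation, s$mode),
      sprintf("  miRNA 5' %s 3'", s$mirna_aln),
      sprintf("           %s", s$annotation),
      sprintf("  site  3' %s 5'", s$site_aln),
      "")
  }))
}
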