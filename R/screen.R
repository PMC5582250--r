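#' GC content of a sequence, percent
#'
#' `100 * (G + C) / (A + C + G + U)`; `N` is excluded from both numerator
#' and denominator.
#'
#' @param seq sequence string (RNA or DNA).
#' @return percent GC (0-100); `NaN` for a sequence of only `N`.
#' @export
gc_percent <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  v <- strsplit(s, "")[[1]]
  v <- v[v != "N"]
  if (!length(v)) return(NaN)
  100 * sum(v %in% c("G", "C")) / length(v)
}

#' Adjusted minimal free energy (AMFE)
#'
#' Energy per 100 nt: `(mfe / length) * 100`, kcal/mol.
#'
#' @param mfe minimal free energy, kcal/mol.
#' @param length sequence length, nt (> 0).
#' @return AMFE in kcal/mol per 100 nt.
#' @export
amfe <- function(mfe, length) {
  stopifnot(length > 0)
  (mfe / length) * 100
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = ((MFE / length) * 100) / GC%`, with GC given as a percent number
#' (50, not 0.5).  Values at or below -0.85 are considered strongly
#' indicative of genuine miRNA precursors.
#'
#' @param mfe minimal free energy, kcal/mol.
#' @param length sequence length, nt (> 0).
#' @param gc GC content in percent.
#' @return MFEI; `NA` when `gc` is zero (reported as a criterion failure
#'   downstream, never a division error).
#' @export
mfei <- function(mfe, length, gc) {
  stopifnot(length > 0)
  if (is.na(gc) || gc == 0) return(NA_real_)
  amfe(mfe, length) / gc
}

#' Excise and fold candidate precursor windows around a homology hit
#'
#' Windows anchored on the mature hit are generated over a geometric length
#' ladder (60, 80, 100, 120, 160, 200, 250, 300 nt, clipped to the
#' configured precursor bounds and to the EST), in two placements per
#' length: mature near the 5' end behind a 10-nt leader, and mature near
#' the 3' end before a 10-nt trailer.  Every window is folded and the
#' best-MFEI window whose hairpin geometry is valid (mature on one arm,
#' mature gap and duplex mismatches within budget) is retained for the hit;
#' if no window is structurally valid the best-MFEI window is kept so the
#' screen can report why it fails.  Ties go to the shorter window.
#'
#' @param hit one row of the [scan_homology()] hit table.
#' @param est the `seq_set` row (or id/seq list) the hit refers to.
#' @param config a [run_config()] list.
#' @return list of `precursor_candidate` objects (length zero or one; empty
#'   when the EST leaves no room for any window).
#' @export
excise_candidates <- function(hit, est, config = run_config()) {
  ladder <- c(60L, 80L, 100L, 120L, 160L, 200L, 250L, 300L)
  ladder <- ladder[ladder >= config$precursor_min & ladder <= config$precursor_max]
  est_seq <- chartr("T", "U", toupper(est$seq[1]))
  L <- nchar(est_seq)
  oriented <- if (hit$strand == "+") est_seq else revcomp(est_seq)
  if (hit$strand == "+") {
    m_start <- hit$est_start; m_end <- hit$est_end
  } else {
    m_start <- L - hit$est_end + 1; m_end <- L - hit$est_start + 1
  }
  mlen <- m_end - m_start + 1
  best <- NULL
  for (w in ladder) {
    for (placement in c("5prime", "3prime")) {
      if (placement == "5prime") {
        ws <- max(1L, m_start - 10L)
        we <- min(L, ws + w - 1L)
      } else {
        we <- min(L, m_end + 10L)
        ws <- max(1L, we - w + 1L)
      }
      wlen <- we - ws + 1L
      if (wlen < config$precursor_min || wlen > config$precursor_max) next
      if (m_start < ws || m_end > we) next
      if (wlen < mlen + 4L) next
      win_seq <- substr(oriented, ws, we)
      st <- fold_rna(win_seq, config$max_loop_size)
      off <- m_start - ws + 1L
      feats <- extract_hairpin(st, c(off, off + mlen - 1L))
      gcv <- gc_percent(win_seq)
      mv <- mfei(st$mfe, wlen, gcv)
      valid <- feats$arm %in% c("5p", "3p") &&
        feats$largest_mature_gap <= config$max_mature_gap &&
        feats$duplex_mismatches <= config$duplex_max_mismatches
      cand <- list(window_start = ws, window_end = we, length = wlen,
                   seq = win_seq, structure = st, features = feats,
                   mfei = if (is.na(mv)) Inf else mv, valid = valid,
                   mature_offset = off)
      if (is.null(best) ||
          (cand$valid && !best$valid) ||
          (cand$valid == best$valid &&
           (cand$mfei < best$mfei ||
            (cand$mfei == best$mfei && cand$length < best$length)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(list())
  # express the window on the EST plus strand for reporting
  if (hit$strand == "+") {
    win_plus <- c(best$window_start, best$window_end)
  } else {
    win_plus <- c(L - best$window_end + 1L, L - best$window_start + 1L)
  }
  cand <- list(candidate_id = paste0(hit$est_id, ":", hit$query_id, ":",
                                     hit$est_start, hit$strand),
               hit = hit,
               est_id = hit$est_id,
               family = hit$family,
               strand = hit$strand,
               window = win_plus,
               precursor_seq = best$seq,
               structure = best$structure,
               mature_offset = best$mature_offset,
               mature_len = mlen,
               features = best$features,
               arm = best$features$arm)
  class(cand) <- "precursor_candidate"
  list(cand)
}

#' Screen a folded precursor candidate against all filtration criteria
#'
#' Criteria, evaluated in order: (1) the mature sits on one arm of the
#' hairpin; (2) the mature contains no unpaired run longer than
#' `max_mature_gap` nt on its own strand; (3) at most
#' `duplex_max_mismatches` mature positions are unpaired against the star
#' arm; (4) MFE at or below `mfe_cutoff`; (5) MFEI at or below
#' `mfei_cutoff`; (6) GC content within `[gc_min, gc_max]`; (7) precursor
#' length within the configured bounds.  The verdict is the conjunction of
#' all seven.  Whether the mature starts with U is recorded but never
#' filtered on, and MFEI at or below `mfei_high_confidence` raises the
#' `high_confidence` flag.  Simple tandem repeats in the precursor are
#' annotated via [find_tandem_repeats()].
#'
#' @param candidate a `precursor_candidate` from [excise_candidates()].
#' @param config a [run_config()] list.
#' @return one-row data.frame (see [write_screen_report()] for the column
#'   order) with the repeat runs attached as attribute `"repeats"`.
#' @export
screen_candidate <- function(candidate, config = run_config()) {
  st <- candidate$structure
  len <- st$length
  gcv <- gc_percent(st$sequence)
  amfev <- amfe(st$mfe, len)
  mfeiv <- mfei(st$mfe, len, gcv)
  f <- candidate$features
  mature_seq <- substr(st$sequence, candidate$mature_offset,
                       candidate$mature_offset + candidate$mature_len - 1)
  crit <- apply_screen_criteria(
    list(arm = f$arm, largest_mature_gap = f$largest_mature_gap,
         duplex_mismatches = f$duplex_mismatches, mfe = st$mfe,
         mfei = mfeiv, gc = gcv, length = len), config)
  reps <- find_tandem_repeats(st$sequence)
  rep_str <- if (nrow(reps) == 0) "" else
    paste(sprintf("(%s)n@%d-%d", reps$unit, reps$begin, reps$end),
          collapse = ";")
  mat <- candidate$hit
  out <- data.frame(
    candidate_id = candidate$candidate_id,
    est_id = candidate$est_id,
    family = candidate$family,
    strand = candidate$strand,
    mature_start = mat$est_start,
    mature_end = mat$est_end,
    arm = f$arm,
    precursor_length = len,
    mfe = st$mfe,
    amfe = amfev,
    mfei = ifelse(is.na(mfeiv), NA_real_, mfeiv),
    gc_percent = gcv,
    starts_with_U = substr(mature_seq, 1, 1) == "U",
    crit_arm = unname(crit["arm"]),
    crit_mature_contiguity = unname(crit["mature_contiguity"]),
    crit_duplex = unname(crit["duplex"]),
    crit_mfe = unname(crit["mfe"]),
    crit_mfei = unname(crit["mfei"]),
    crit_gc = unname(crit["gc"]),
    crit_length = unname(crit["length"]),
    high_confidence = is_high_confidence(mfeiv, config),
    repeat_annotations = rep_str,
    verdict = all(crit),
    stringsAsFactors = FALSE)
  attr(out, "repeats") <- reps
  out
}

#' Apply the filtration thresholds to candidate statistics
#'
#' The pure threshold logic behind [screen_candidate()]: criteria on arm
#' placement, mature contiguity, duplex mismatches, MFE, MFEI, GC window
#' and precursor length.  MFE and MFEI are "keep if at or below the
#' cutoff" (more negative passes); a missing MFEI (zero GC) fails its
#' criterion rather than raising a division error.
#'
#' @param stats list with `arm`, `largest_mature_gap`,
#'   `duplex_mismatches`, `mfe`, `mfei`, `gc`, `length`.
#' @param config a [run_config()] list.
#' @return named logical vector of the seven criteria.
#' @export
apply_screen_criteria <- function(stats, config = run_config()) {
  c(arm = stats$arm %in% c("5p", "3p"),
    mature_contiguity = stats$largest_mature_gap <= config$max_mature_gap,
    duplex = stats$duplex_mismatches <= config$duplex_max_mismatches,
    mfe = stats$mfe <= config$mfe_cutoff,
    mfei = !is.na(stats$mfei) && stats$mfei <= config$mfei_cutoff,
    gc = !is.na(stats$gc) && stats$gc >= config$gc_min &&
      stats$gc <= config$gc_max,
    length = stats$length >= config$precursor_min &&
      stats$length <= config$precursor_max)
}

#' High-confidence MFEI flag
#'
#' MFEI values at or below `mfei_high_confidence` (default -0.85) are
#' strongly indicative of genuine miRNA precursors; the flag annotates,
#' never filters.
#'
#' @param mfei_value MFEI of a candidate.
#' @param config a [run_config()] list.
#' @return logical.
#' @export
is_high_confidence <- function(mfei_value, config = run_config()) {
  !is.na(mfei_value) && mfei_value <= config$mfei_high_confidence
}

#' Find maximal exact tandem repeats
#'
#' Reports every maximal exact tandem run with a primitive repeat unit of
#' `min_unit`-`max_unit` nt, at least `min_copies` copies and spanning at
#' least `min_span` nt.  The unit is reported as its lexicographically
#' smallest rotation; overlapping runs with different units are all
#' reported.
#'
#' @param seq sequence string.
#' @param min_unit,max_unit unit length bounds, nt (defaults 1 and 6).
#' @param min_copies minimum copy number (default 3).
#' @param min_span minimum run span, nt (default 12).
#' @return data.frame: `unit`, `begin`, `end` (1-based inclusive),
#'   `copies` (span/unit, fractional copies allowed), `span`.
#' @examples
#' find_tandem_repeats("AGAAGAAGAAGA")
#' @export
find_tandem_repeats <- function(seq, min_unit = 1, max_unit = 6,
                                min_copies = 3, min_span = 12) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  runs <- list()
  for (u in min_unit:max_unit) {
    if (n < 2 * u) next
    eq <- s[seq_len(n - u)] == s[seq_len(n - u) + u]
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      a <- pos[k]
      span <- r$lengths[k] + u
      b <- a + span - 1
      copies <- span / u
      if (span < min_span || copies < min_copies) next
      unit <- paste(s[a:(a + u - 1)], collapse = "")
      if (!is_primitive_unit(unit)) next
      runs[[length(runs) + 1]] <- data.frame(
        unit = smallest_rotation(unit), begin = a, end = b,
        copies = copies, span = span, stringsAsFactors = FALSE)
    }
  }
  if (!length(runs)) {
    return(data.frame(unit = character(0), begin = integer(0),
                      end = integer(0), copies = numeric(0),
                      span = integer(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, runs))
  out <- out[order(out$begin, out$end, out$unit), ]
  rownames(out) <- NULL
  out
}

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0) {
      if (paste(rep(substr(unit, 1, d), u / d), collapse = "") == unit)
        return(FALSE)
    }
  }
  TRUE
}

smallest_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(k) {
    paste0(substr(unit, k, u), substr(unit, 1, k - 1))
  }, character(1))
  sort(rots)[1]
}
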